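## Canonical on-disk trajectory format: delimited text (CSV), long/tidy
## layout so rosters of any size need no schema change. Header row, columns
## session_id, tick, time_s, individual_id, x_cm, y_cm, z_cm; a missing
## (occluded) sample keeps its row with empty x/y/z cells. Units are cm and
## seconds throughout; x runs along the 270 cm wall, y along the 150 cm
## wall, z vertical, origin at a floor corner.

trajectoryColumns <- c("session_id", "tick", "time_s", "individual_id",
                       "x_cm", "y_cm", "z_cm")

#' Write a session to the canonical CSV trajectory format
#'
#' One row per (tick, individual); missing samples have empty coordinate
#' cells. Coordinates are written with full precision so
#' \code{\link{readSession}} round-trips bit-exactly.
#'
#' @param t a \linkS4class{TrajectorySet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSession <- function(t, path) {
  stopifnot(is(t, "TrajectorySet"))
  n <- nTicks(t)
  k <- length(t@roster)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  rows <- character(n * k)
  line <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(trajectoryColumns, collapse = ","), con)
  for (id in t@roster) {
    p <- t@positions[[id]]
    if (n == 0L) next
    chunk <- paste(t@sessionId, seq_len(n), sprintf("%.17g", t@timesS), id,
                   fmt(p[, 1]), fmt(p[, 2]), fmt(p[, 3]), sep = ",")
    rows[line + seq_len(n)] <- chunk
    line <- line + n
  }
  if (line > 0L) writeLines(rows[seq_len(line)], con)
  invisible(path)
}

#' Read a session from the canonical CSV trajectory format
#'
#' Validates the header, time monotonicity and spacing, and that all
#' non-missing coordinates lie inside the cage box; violations raise a parse
#' error naming the offending file line.
#'
#' @param path input file path.
#' @param geometry the \linkS4class{CageGeometry} the coordinates must lie
#'   in (default study cage).
#' @param rateHz expected sampling rate; if NULL (default), inferred from
#'   the time column.
#' @return A \linkS4class{TrajectorySet}.
#' @export
readSession <- function(path, geometry = cageGeometry(), rateHz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(hdr, trajectoryColumns))
    stop("parse error in ", path, " line 1: header must be '",
         paste(trajectoryColumns, collapse = ","), "'", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(session_id = "character",
                                       individual_id = "character"))
  if (nrow(df) == 0L) {
    return(trajectorySet("empty", character(0), 15,
                         structure(list(), names = character(0)), geometry))
  }
  sessionId <- df$session_id[1L]
  roster <- unique(df$individual_id)
  box <- c(geometry@lengthCm, geometry@widthCm, geometry@heightCm)

  # per-individual structural checks with file line numbers (header = line 1)
  fileLine <- seq_len(nrow(df)) + 1L
  for (id in roster) {
    sel <- df$individual_id == id
    tt <- df$time_s[sel]
    if (length(tt) > 1L) {
      bad <- which(diff(tt) <= 0)
      if (length(bad))
        stop("parse error in ", path, " line ",
             fileLine[sel][bad[1L] + 1L],
             ": time not strictly increasing for individual '", id, "'",
             call. = FALSE)
    }
    for (j in 1:3) {
      v <- df[[c("x_cm", "y_cm", "z_cm")[j]]][sel]
      bad <- which(!is.na(v) & (v < -1e-9 | v > box[j] + 1e-9))
      if (length(bad))
        stop("parse error in ", path, " line ", fileLine[sel][bad[1L]],
             ": coordinate outside the cage box", call. = FALSE)
    }
  }

  timesS <- sort(unique(df$time_s))
  n <- length(timesS)
  if (is.null(rateHz)) {
    rateHz <- if (n > 1L) 1 / stats::median(diff(timesS)) else 15
    rateHz <- round(rateHz, 6)
  }
  positions <- lapply(roster, function(id) {
    sel <- df$individual_id == id
    m <- matrix(NA_real_, n, 3)
    rowIdx <- match(df$time_s[sel], timesS)
    m[rowIdx, ] <- as.matrix(df[sel, c("x_cm", "y_cm", "z_cm")])
    # a partially tracked sample is treated as missing
    part <- rowSums(is.na(m)) %in% c(1L, 2L)
    m[part, ] <- NA_real_
    m
  })
  names(positions) <- roster
  trajectorySet(sessionId, roster, rateHz, positions, geometry,
                timesS = timesS)
}

#' Retain only ticks where both individuals are tracked
#'
#' @param t a \linkS4class{TrajectorySet}.
#' @param a,b individual labels (must be in the roster).
#' @return List with \code{ticks} (original 1-based tick indices), and
#'   \code{a}, \code{b}: position matrices restricted to those ticks.
#' @export
dropMissingPairwise <- function(t, a, b) {
  stopifnot(is(t, "TrajectorySet"))
  for (id in c(a, b))
    if (!id %in% t@roster)
      stop("unknown individual '", id, "'", call. = FALSE)
  pa <- t@positions[[a]]
  pb <- t@positions[[b]]
  keep <- which(stats::complete.cases(pa) & stats::complete.cases(pb))
  list(ticks = as.integer(keep),
       a = pa[keep, , drop = FALSE],
       b = pb[keep, , drop = FALSE])
}

#' Build a session catalog
#'
#' Labels every session by social context: \code{"quadruple"} when the full
#' roster is present, \code{"triplet:<removed>"} when exactly one member is
#' absent. The full roster defaults to the union of all session rosters.
#'
#' @param sessions named list of \linkS4class{TrajectorySet}.
#' @param fullRoster optional explicit full roster.
#' @param paths optional file paths per session (same order).
#' @return data.frame with columns session_id, context, n_individuals,
#'   roster (comma-separated), path.
#' @export
sessionCatalog <- function(sessions, fullRoster = NULL, paths = NA_character_) {
  ids <- vapply(sessions, sessionId, character(1))
  if (anyDuplicated(ids)) stop("duplicate session ids", call. = FALSE)
  if (is.null(fullRoster))
    fullRoster <- Reduce(union, lapply(sessions, roster))
  context <- vapply(sessions, function(s) {
    rem <- setdiff(fullRoster, roster(s))
    if (length(rem) == 0L) "quadruple"
    else if (length(rem) == 1L) paste0("triplet:", rem)
    else paste0("other:", paste(rem, collapse = "+"))
  }, character(1))
  data.frame(session_id = ids, context = context,
             n_individuals = vapply(sessions, function(s)
               length(roster(s)), integer(1)),
             roster = vapply(sessions, function(s)
               paste(roster(s), collapse = ","), character(1)),
             path = rep_len(paths, length(sessions)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a session catalog as JSON
#'
#' @param catalog a catalog data.frame from \code{\link{sessionCatalog}}.
#' @param path JSON file path.
#' @return \code{writeSessionCatalog}: the path, invisibly;
#'   \code{readSessionCatalog}: the catalog data.frame.
#' @export
writeSessionCatalog <- function(catalog, path) {
  jsonlite::write_json(catalog, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSessionCatalog
#' @export
readSessionCatalog <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (is.null(df$path)) df$path <- NA_character_
  nr <- vapply(strsplit(df$roster, ","), length, integer(1))
  if (any(nr != df$n_individuals))
    stop("catalog error: context/roster size mismatch", call. = FALSE)
  df
}
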