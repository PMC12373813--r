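## Occupancy maps and the social-context influence analysis.
##
## An occupancy map discretizes the horizontal plane (z marginalized) into a
## 16 x 29 grid -- 16 bins along the 150 cm (y) axis, 29 along the 270 cm
## (x) axis, cells of about 9.3 cm -- and records the fraction of tracked
## time spent in each cell. The context-change index D between two maps of
## the same individual is the mean over cells of the absolute difference
## (the L1 difference divided by the number of cells). Because different
## conditions contribute different numbers of session pairs, inference uses
## a resampled t scheme: repeatedly draw equal numbers of baseline and
## condition D values with replacement, t-test each draw, and average the p
## values.

#' Compute a normalized occupancy map
#'
#' Time fractions over a horizontal grid (default 16 bins over the short
#' axis x 29 bins over the long axis). The denominator is the number of
#' non-missing samples, so occlusion gaps do not deflate the map; with full
#' tracking this equals session duration.
#'
#' @param t a \linkS4class{TrajectorySet}.
#' @param individual roster member to map.
#' @param nXBins,nYBins grid dimensions (long, short axis).
#' @return An \linkS4class{OccupancyMap} (grid rows = y bins, cols = x bins).
#' @examples
#' setup <- defaultStudySetup()
#' ts <- generateSession(setup$geometry, setup$footprints, setup$social,
#'                       sessionSpec(setup$roster, 60, seed = 3))
#' occupancyMap(ts, "m1")
#' @export
occupancyMap <- function(t, individual, nXBins = 29L, nYBins = 16L) {
  stopifnot(is(t, "TrajectorySet"))
  p <- positions(t, individual)
  ok <- stats::complete.cases(p)
  if (!any(ok))
    stop("cannot build occupancy map: all samples missing for '",
         individual, "'", call. = FALSE)
  g <- geometry(t)
  xEdges <- seq(0, g@lengthCm, length.out = nXBins + 1L)
  yEdges <- seq(0, g@widthCm, length.out = nYBins + 1L)
  xi <- findInterval(p[ok, 1L], xEdges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  yi <- findInterval(p[ok, 2L], yEdges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0, nYBins, nXBins)
  tab <- table(factor(yi, levels = seq_len(nYBins)),
               factor(xi, levels = seq_len(nXBins)))
  counts[] <- as.numeric(tab)
  new("OccupancyMap", individualId = individual, sessionId = sessionId(t),
      grid = counts / sum(counts), xEdges = xEdges, yEdges = yEdges)
}

#' Context-change index D between two occupancy maps
#'
#' D is the mean over grid cells of the absolute difference between the two
#' normalized maps of one individual. It is symmetric, non-negative, and
#' zero exactly when the maps are identical.
#'
#' @param mapA,mapB \linkS4class{OccupancyMap}s of the same individual with
#'   identical grid shape.
#' @return The scalar D.
#' @export
contextChange <- function(mapA, mapB) {
  stopifnot(is(mapA, "OccupancyMap"), is(mapB, "OccupancyMap"))
  if (!identical(dim(mapA@grid), dim(mapB@grid)))
    stop("occupancy grids have different shapes", call. = FALSE)
  if (mapA@individualId != mapB@individualId)
    stop("context change is defined between maps of the same individual",
         call. = FALSE)
  mean(abs(mapA@grid - mapB@grid))
}

#' Context-change table over a study
#'
#' For every individual: D between every unordered pair of quadruple
#' sessions (the within-context baseline, condition "4in-vs-4in") and D
#' between every (quadruple, triplet) session pair for each removal
#' condition the individual witnessed (condition "4in-vs-triplet:<removed>").
#'
#' @param sessions named list of \linkS4class{TrajectorySet} covering at
#'   least two quadruple sessions.
#' @param fullRoster optional explicit full roster (default: union).
#' @param nXBins,nYBins occupancy grid dimensions.
#' @return data.frame with columns individual, condition, session_m,
#'   session_n, D.
#' @export
contextChangeTable <- function(sessions, fullRoster = NULL,
                               nXBins = 29L, nYBins = 16L) {
  catalog <- sessionCatalog(sessions, fullRoster)
  if (is.null(fullRoster))
    fullRoster <- Reduce(union, lapply(sessions, roster))
  quadIds <- catalog$session_id[catalog$context == "quadruple"]
  if (length(quadIds) < 2L)
    stop("need at least two quadruple sessions", call. = FALSE)
  bySession <- stats::setNames(sessions,
                               vapply(sessions, sessionId, character(1)))
  for (id in quadIds) {
    absent <- setdiff(fullRoster, roster(bySession[[id]]))
    if (length(absent))
      stop("catalog error: individual(s) ",
           paste(absent, collapse = ", "),
           " absent from quadruple session '", id, "'", call. = FALSE)
  }
  maps <- lapply(bySession, function(s) {
    ms <- lapply(roster(s), function(ind)
      occupancyMap(s, ind, nXBins = nXBins, nYBins = nYBins))
    stats::setNames(ms, roster(s))
  })

  out <- list()
  for (ind in fullRoster) {
    qp <- utils::combn(quadIds, 2L)
    for (c in seq_len(ncol(qp))) {
      m <- qp[1L, c]; n2 <- qp[2L, c]
      out[[length(out) + 1L]] <- data.frame(
        individual = ind, condition = "4in-vs-4in",
        session_m = m, session_n = n2,
        D = contextChange(maps[[m]][[ind]], maps[[n2]][[ind]]),
        stringsAsFactors = FALSE)
    }
    for (rm in setdiff(fullRoster, ind)) {
      cond <- paste0("triplet:", rm)
      tripIds <- catalog$session_id[catalog$context == cond]
      for (ti in tripIds) {
        if (!ind %in% roster(bySession[[ti]]))
          stop("catalog error: individual '", ind,
               "' absent from session '", ti, "'", call. = FALSE)
        for (qi in quadIds) {
          out[[length(out) + 1L]] <- data.frame(
            individual = ind, condition = paste0("4in-vs-", cond),
            session_m = qi, session_n = ti,
            D = contextChange(maps[[qi]][[ind]], maps[[ti]][[ind]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Resampled t test for context-change values
#'
#' Each repeat draws \code{nPerGroup} values with replacement from the
#' baseline and condition groups, computes a Welch two-sample t statistic,
#' and records t and p; inference is based on the average p over repeats.
#' Drawing with replacement is required because the groups can hold fewer
#' values than \code{nPerGroup}. Note the scheme inflates the effective n
#' relative to the true number of session pairs; see the package vignette.
#'
#' @param baselineD,conditionD numeric vectors of D values (non-empty).
#' @param nRepeats number of resampling repeats (default 200).
#' @param nPerGroup draws per group per repeat (default 100).
#' @param seed integer seed (results are deterministic given it).
#' @return A \linkS4class{PermutationTestResult}.
#' @export
permutationContextTest <- function(baselineD, conditionD, nRepeats = 200L,
                                   nPerGroup = 100L, seed = 1L) {
  if (length(baselineD) == 0L || length(conditionD) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  set.seed(seed)
  tv <- pv <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    a <- sample(baselineD, nPerGroup, replace = TRUE)
    b <- sample(conditionD, nPerGroup, replace = TRUE)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate draw: identical constants carry no evidence
      tv[r] <- 0; pv[r] <- 1
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      tv[r] <- unname(tt$statistic); pv[r] <- tt$p.value
    }
  }
  new("PermutationTestResult", meanP = mean(pv), tValues = tv,
      pValues = pv, nRepeats = as.integer(nRepeats),
      nPerGroup = as.integer(nPerGroup))
}

#' Per-session median positions with rank-based group comparison
#'
#' Coordinate-wise medians over non-missing samples for every individual in
#' every session, followed per axis by a Friedman rank test across
#' individuals with sessions as blocks and pairwise Wilcoxon signed-rank
#' follow-ups. Sessions missing any of the compared individuals are excluded
#' from the tests with a warning.
#'
#' @param sessions named list of \linkS4class{TrajectorySet} (>= 2).
#' @param individuals individuals to compare (default: union of rosters).
#' @return List with \code{medians} (data.frame session_id, individual, x_cm,
#'   y_cm, z_cm), \code{friedman} (data.frame axis, statistic, df, p_value),
#'   \code{pairwise} (data.frame axis, ind_a, ind_b, V, p_value).
#' @export
medianPositions <- function(sessions, individuals = NULL) {
  if (length(sessions) < 2L)
    stop("need at least two sessions", call. = FALSE)
  if (is.null(individuals))
    individuals <- Reduce(union, lapply(sessions, roster))
  med <- do.call(rbind, lapply(sessions, function(s) {
    do.call(rbind, lapply(roster(s), function(ind) {
      p <- positions(s, ind)
      ok <- stats::complete.cases(p)
      data.frame(session_id = sessionId(s), individual = ind,
                 x_cm = stats::median(p[ok, 1L]),
                 y_cm = stats::median(p[ok, 2L]),
                 z_cm = stats::median(p[ok, 3L]),
                 stringsAsFactors = FALSE)
    }))
  }))
  row.names(med) <- NULL

  complete <- vapply(sessions, function(s)
    all(individuals %in% roster(s)), logical(1))
  if (any(!complete))
    warning(sum(!complete), " session(s) excluded from rank tests ",
            "(individual(s) absent): ",
            paste(vapply(sessions[!complete], sessionId, character(1)),
                  collapse = ", "), call. = FALSE)
  keep <- med$session_id %in%
    vapply(sessions[complete], sessionId, character(1)) &
    med$individual %in% individuals
  sub <- med[keep, , drop = FALSE]

  friedman <- NULL; pairwise <- NULL
  if (length(unique(sub$session_id)) >= 2L && length(individuals) >= 2L) {
    for (ax in c("x_cm", "y_cm", "z_cm")) {
      ft <- stats::friedman.test(sub[[ax]],
                                 groups = factor(sub$individual),
                                 blocks = factor(sub$session_id))
      friedman <- rbind(friedman, data.frame(
        axis = ax, statistic = unname(ft$statistic),
        df = unname(ft$parameter), p_value = ft$p.value,
        stringsAsFactors = FALSE))
      prs <- utils::combn(sort(unique(sub$individual)), 2L)
      for (c in seq_len(ncol(prs))) {
        a <- prs[1L, c]; b <- prs[2L, c]
        va <- sub[[ax]][sub$individual == a][order(sub$session_id[sub$individual == a])]
        vb <- sub[[ax]][sub$individual == b][order(sub$session_id[sub$individual == b])]
        wt <- stats::wilcox.test(va, vb, paired = TRUE, exact = FALSE)
        pairwise <- rbind(pairwise, data.frame(
          axis = ax, ind_a = a, ind_b = b,
          V = unname(wt$statistic), p_value = wt$p.value,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(medians = med, friedman = friedman, pairwise = pairwise)
}
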