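## Interpersonal-distance analyses: distance series, distribution shape,
## data-driven affiliation thresholds, affiliative strength/weakness, and
## close-proximity bout (chunk) statistics.
##
## The affiliation thresholds are read off the smoothed average distance
## distribution: the close cutoff is the first local minimum after the
## close-proximity peak, the far cutoff the first local minimum after the
## main right-side peak (73 cm and 185 cm on the study's own recordings).
## Chunks are maximal runs of consecutive samples below a 50 cm criterion;
## a single below-threshold sample counts as a one-sample chunk.

#' Interpersonal distance series for a pair
#'
#' 3D Euclidean distance at every tick where both individuals are tracked;
#' tick indices are retained so bout structure survives occlusion gaps.
#'
#' @param t a \linkS4class{TrajectorySet}.
#' @param a,b distinct roster members.
#' @return A \linkS4class{DistanceSeries}.
#' @examples
#' setup <- defaultStudySetup()
#' ts <- generateSession(setup$geometry, setup$footprints, setup$social,
#'                       sessionSpec(setup$roster, 60, seed = 5))
#' distanceSeries(ts, "m1", "m2")
#' @export
distanceSeries <- function(t, a, b) {
  if (a == b) stop("a pair needs two distinct individuals", call. = FALSE)
  pr <- dropMissingPairwise(t, a, b)
  d <- sqrt(rowSums((pr$a - pr$b)^2))
  new("DistanceSeries", pair = c(a, b), ticks = pr$ticks, dCm = d,
      rateHz = rateHz(t))
}

#' Session-averaged pairwise distance matrix with across-session comparisons
#'
#' Entry (a, b) is the mean over sessions of the session-mean distance
#' between a and b (sessions where the pair is never co-tracked are skipped
#' and the entry flagged NA). Pairs of pair-entries are then compared with
#' paired t tests using sessions as samples.
#'
#' @param sessions named list of \linkS4class{TrajectorySet} (>= 2).
#' @param rankOrder optional individual ordering (e.g. dominance rank) for
#'   the matrix rows/columns; default union of rosters.
#' @return List with \code{matrix} (symmetric mean-distance matrix),
#'   \code{perSession} (data.frame session_id, pair, mean_cm), and
#'   \code{comparisons} (data.frame pair_1, pair_2, t, df, p_value).
#' @export
meanDistanceMatrix <- function(sessions, rankOrder = NULL) {
  if (length(sessions) < 2L)
    stop("need at least two sessions", call. = FALSE)
  ids <- if (is.null(rankOrder))
    Reduce(union, lapply(sessions, roster)) else rankOrder
  prs <- utils::combn(ids, 2L)
  perSession <- list()
  for (s in sessions) {
    for (c in seq_len(ncol(prs))) {
      a <- prs[1L, c]; b <- prs[2L, c]
      if (!all(c(a, b) %in% roster(s))) next
      ds <- distanceSeries(s, a, b)
      if (length(distances(ds)) == 0L) next
      perSession[[length(perSession) + 1L]] <- data.frame(
        session_id = sessionId(s), pair = paste(a, b, sep = "-"),
        mean_cm = mean(distances(ds)), stringsAsFactors = FALSE)
    }
  }
  perSession <- do.call(rbind, perSession)
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (c in seq_len(ncol(prs))) {
    a <- prs[1L, c]; b <- prs[2L, c]
    key <- paste(a, b, sep = "-")
    v <- perSession$mean_cm[perSession$pair == key]
    if (length(v)) m[a, b] <- m[b, a] <- mean(v)
    else warning("pair ", key, " never co-tracked; entry left NA",
                 call. = FALSE)
  }
  pairKeys <- apply(prs, 2L, paste, collapse = "-")
  comparisons <- NULL
  for (i in seq_along(pairKeys)) for (j in seq_along(pairKeys)) {
    if (j <= i) next
    si <- perSession[perSession$pair == pairKeys[i], ]
    sj <- perSession[perSession$pair == pairKeys[j], ]
    common <- intersect(si$session_id, sj$session_id)
    if (length(common) < 2L) next
    vi <- si$mean_cm[match(common, si$session_id)]
    vj <- sj$mean_cm[match(common, sj$session_id)]
    if (stats::sd(vi - vj) == 0) next
    tt <- stats::t.test(vi, vj, paired = TRUE)
    comparisons <- rbind(comparisons, data.frame(
      pair_1 = pairKeys[i], pair_2 = pairKeys[j],
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, stringsAsFactors = FALSE))
  }
  list(matrix = m, perSession = perSession, comparisons = comparisons)
}

#' Binned and smoothed interpersonal-distance distribution
#'
#' Histogram density on a regular distance grid plus a fixed-bandwidth
#' Gaussian kernel smoothing of it; both integrate to 1 over the grid.
#'
#' @param d numeric distances (cm), or a \linkS4class{DistanceSeries}, or a
#'   list of either to pool.
#' @param binWidthCm histogram bin width (default 1 cm).
#' @param bwCm Gaussian smoothing bandwidth (default 5 cm).
#' @param rangeCm distance range covered by the grid (default c(0, 368),
#'   the default cage diagonal rounded up).
#' @return data.frame of class \code{"distanceDensity"} with columns
#'   \code{mid} (bin centers), \code{raw} (histogram density),
#'   \code{smooth} (kernel-smoothed density).
#' @export
distanceDistribution <- function(d, binWidthCm = 1, bwCm = 5,
                                 rangeCm = c(0, 368)) {
  if (is(d, "DistanceSeries")) d <- distances(d)
  if (is.list(d))
    d <- unlist(lapply(d, function(x)
      if (is(x, "DistanceSeries")) distances(x) else x))
  if (length(d) == 0L) stop("empty distance series", call. = FALSE)
  edges <- seq(rangeCm[1L], rangeCm[2L] + binWidthCm, by = binWidthCm)
  mids <- edges[-length(edges)] + binWidthCm / 2
  h <- findInterval(pmin(pmax(d, rangeCm[1L]), rangeCm[2L]), edges,
                    rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(h, nbins = length(mids))
  raw <- counts / sum(counts) / binWidthCm
  # discrete Gaussian smoothing of the histogram, kernel renormalized at
  # the boundaries so mass is conserved
  halfw <- ceiling(4 * bwCm / binWidthCm)
  kern <- stats::dnorm(seq(-halfw, halfw) * binWidthCm, sd = bwCm)
  sm <- stats::filter(c(rep(0, halfw), raw, rep(0, halfw)), kern / sum(kern))
  sm <- as.numeric(sm[(halfw + 1L):(halfw + length(raw))])
  wt <- stats::filter(c(rep(0, halfw), rep(1, length(raw)), rep(0, halfw)),
                      kern / sum(kern))
  wt <- as.numeric(wt[(halfw + 1L):(halfw + length(raw))])
  sm <- sm / wt
  sm <- sm / sum(sm * binWidthCm)
  out <- data.frame(mid = mids, raw = raw, smooth = sm)
  class(out) <- c("distanceDensity", "data.frame")
  out
}

localExtrema <- function(v) {
  # indices of strict-left / weak-right local maxima and minima
  n <- length(v)
  dl <- c(Inf, diff(v))        # v[i] - v[i-1]
  dr <- c(diff(v), -Inf)       # v[i+1] - v[i]
  list(max = which(dl > 0 & dr <= 0), min = which(dl < 0 & dr >= 0))
}

#' Data-driven affiliation thresholds from a distance distribution
#'
#' Locates modes of the smoothed density (local maxima at or above
#' \code{minModeFrac} of the global maximum). The close threshold is the
#' first local minimum after the first (close-proximity) mode; the far
#' threshold is the first local minimum after the main right-side mode
#' (the highest mode beyond the close threshold). A unimodal density has no
#' close threshold and is returned flagged; modes beyond the far threshold
#' (avoidance peaks) are reported.
#'
#' @param dens a \code{"distanceDensity"} data.frame from
#'   \code{\link{distanceDistribution}}.
#' @param minModeFrac minimum relative height for a mode (default 0.05).
#' @return List with \code{closeCm}, \code{farCm} (NA when undefined),
#'   \code{modesCm} (mode locations), \code{unimodal} flag.
#' @export
findAffiliationThresholds <- function(dens, minModeFrac = 0.05) {
  stopifnot(inherits(dens, "distanceDensity"))
  v <- dens$smooth
  ex <- localExtrema(v)
  modes <- ex$max[v[ex$max] >= minModeFrac * max(v)]
  mins <- ex$min
  if (length(modes) <= 1L) {
    return(list(closeCm = NA_real_,
                farCm = NA_real_,
                modesCm = dens$mid[modes],
                unimodal = TRUE))
  }
  firstMode <- modes[1L]
  closeIdx <- mins[mins > firstMode]
  closeIdx <- if (length(closeIdx)) closeIdx[1L] else NA_integer_
  closeCm <- if (is.na(closeIdx)) NA_real_ else dens$mid[closeIdx]
  rightModes <- modes[modes > closeIdx]
  farCm <- NA_real_
  if (!is.na(closeIdx) && length(rightModes)) {
    mainRight <- rightModes[which.max(v[rightModes])]
    farIdx <- mins[mins > mainRight]
    if (length(farIdx)) farCm <- dens$mid[farIdx[1L]]
  }
  list(closeCm = closeCm, farCm = farCm, modesCm = dens$mid[modes],
       unimodal = FALSE)
}

#' Preset affiliation thresholds
#'
#' The thresholds recovered on the study's own recordings (close 73 cm,
#' far 185 cm), plus the alternative 80 cm close cutoff corresponding to
#' the cumulative-sum range used for the strength metric.
#'
#' @param close either \code{"73"} (threshold definition, default) or
#'   \code{"80"} (cumulative-sum range).
#' @return List with \code{closeCm} and \code{farCm}.
#' @export
presetThresholds <- function(close = c("73", "80")) {
  close <- match.arg(close)
  list(closeCm = as.numeric(close), farCm = 185)
}

#' Affiliative strength of an individual
#'
#' Total time the individual spends closer than \code{closeCm} to each
#' partner, summed over all partners (so simultaneous proximity to two
#' partners counts twice, once per pair).
#'
#' @param t a \linkS4class{TrajectorySet}.
#' @param individual roster member.
#' @param closeCm close-proximity cutoff in cm (default the 73 cm preset).
#' @param perPartner return the per-partner breakdown instead of the sum.
#' @return Time in seconds (or a named vector if \code{perPartner}).
#' @export
affiliativeStrength <- function(t, individual, closeCm = 73,
                                perPartner = FALSE) {
  partnerTime(t, individual, function(d) d < closeCm, perPartner)
}

#' Affiliative weakness of an individual
#'
#' Total time spent farther than \code{farCm} from each partner, summed
#' over partners.
#'
#' @inheritParams affiliativeStrength
#' @param farCm avoidance cutoff in cm (default 185).
#' @return Time in seconds (or a named vector if \code{perPartner}).
#' @export
affiliativeWeakness <- function(t, individual, farCm = 185,
                                perPartner = FALSE) {
  partnerTime(t, individual, function(d) d > farCm, perPartner)
}

partnerTime <- function(t, individual, cond, perPartner) {
  if (!individual %in% roster(t))
    stop("unknown individual '", individual, "'", call. = FALSE)
  partners <- setdiff(roster(t), individual)
  v <- vapply(partners, function(p) {
    d <- distances(distanceSeries(t, individual, p))
    sum(cond(d)) / rateHz(t)
  }, numeric(1))
  if (perPartner) v else sum(v)
}

#' Close-proximity chunks (bouts) for a pair
#'
#' Maximal runs of consecutive ticks with distance below the threshold.
#' A missing tick (occlusion gap) breaks a run unless the gap is at most
#' \code{bridgeGapTicks} ticks long (default 0: conservative, no bridging).
#' A single qualifying sample is a one-sample chunk.
#'
#' @param series a \linkS4class{DistanceSeries}.
#' @param thresholdCm distance criterion in cm (default 50).
#' @param bridgeGapTicks missing-gap length (ticks) still treated as
#'   continuous (default 0).
#' @return A \linkS4class{ChunkSet} (durations in seconds).
#' @export
proximityChunks <- function(series, thresholdCm = 50, bridgeGapTicks = 0L) {
  stopifnot(is(series, "DistanceSeries"))
  tk <- ticks(series)
  below <- distances(series) < thresholdCm
  durations <- integer(0)
  run <- 0L; lastTick <- NA_integer_
  for (i in seq_along(tk)) {
    if (below[i]) {
      contiguous <- !is.na(lastTick) &&
        (tk[i] - lastTick) <= (1L + bridgeGapTicks)
      run <- if (run > 0L && contiguous) run + 1L else {
        if (run > 0L) durations <- c(durations, run)
        1L
      }
      lastTick <- tk[i]
    } else {
      if (run > 0L) durations <- c(durations, run)
      run <- 0L; lastTick <- NA_integer_
    }
  }
  if (run > 0L) durations <- c(durations, run)
  new("ChunkSet", pair = series@pair,
      durationsS = durations / series@rateHz,
      thresholdCm = thresholdCm, rateHz = series@rateHz)
}

#' Log-scale chunk-duration histograms with pairwise KS comparisons
#'
#' Chunk durations are log10-transformed and binned into logarithmically
#' spaced bins between one sample and the longest observed chunk; every
#' pair of pairs is compared with a two-sample Kolmogorov-Smirnov test,
#' optionally restricted to duration intervals.
#'
#' @param chunksByPair named list of \linkS4class{ChunkSet} (>= 2 non-empty;
#'   empty sets are excluded with a warning).
#' @param nBins number of log-spaced bins (default 20).
#' @param intervalsS optional list of c(lo, hi) duration intervals in
#'   seconds; default one interval spanning everything.
#' @return List with \code{histograms} (data.frame pair, bin_lo_s, bin_hi_s,
#'   count) and \code{ks} (data.frame pair_1, pair_2, interval_lo_s,
#'   interval_hi_s, statistic, p_value).
#' @export
chunkHistogramsCompare <- function(chunksByPair, nBins = 20L,
                                   intervalsS = NULL) {
  if (is.null(names(chunksByPair)))
    names(chunksByPair) <- vapply(chunksByPair, function(cs)
      paste(cs@pair, collapse = "-"), character(1))
  empty <- vapply(chunksByPair, function(cs)
    length(cs@durationsS) == 0L, logical(1))
  if (any(empty)) {
    warning("excluding pair(s) with no chunks: ",
            paste(names(chunksByPair)[empty], collapse = ", "),
            call. = FALSE)
    chunksByPair <- chunksByPair[!empty]
  }
  if (length(chunksByPair) < 2L)
    stop("need chunk sets for at least two pairs", call. = FALSE)
  allDur <- unlist(lapply(chunksByPair, chunkDurations))
  rate <- chunksByPair[[1L]]@rateHz
  lo <- 1 / rate
  hi <- max(allDur)
  if (hi <= lo) hi <- lo * 10
  edges <- 10^seq(log10(lo), log10(hi), length.out = nBins + 1L)
  hists <- do.call(rbind, lapply(names(chunksByPair), function(nm) {
    d <- chunkDurations(chunksByPair[[nm]])
    idx <- findInterval(d, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    data.frame(pair = nm, bin_lo_s = edges[-length(edges)],
               bin_hi_s = edges[-1L],
               count = tabulate(idx, nbins = nBins),
               stringsAsFactors = FALSE)
  }))
  if (is.null(intervalsS)) intervalsS <- list(c(0, Inf))
  ks <- NULL
  nms <- names(chunksByPair)
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    for (iv in intervalsS) {
      di <- chunkDurations(chunksByPair[[nms[i]]])
      dj <- chunkDurations(chunksByPair[[nms[j]]])
      di <- di[di >= iv[1L] & di <= iv[2L]]
      dj <- dj[dj >= iv[1L] & dj <= iv[2L]]
      if (length(di) < 2L || length(dj) < 2L) {
        warning("KS skipped for ", nms[i], " vs ", nms[j],
                " (fewer than 2 chunks in interval)", call. = FALSE)
        next
      }
      kt <- suppressWarnings(stats::ks.test(di, dj))
      ks <- rbind(ks, data.frame(
        pair_1 = nms[i], pair_2 = nms[j],
        interval_lo_s = iv[1L], interval_hi_s = iv[2L],
        statistic = unname(kt$statistic), p_value = kt$p.value,
        stringsAsFactors = FALSE))
    }
  }
  list(histograms = hists, ks = ks)
}
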