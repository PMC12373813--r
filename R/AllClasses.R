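#' @import methods
NULL

#' Cage geometry
#'
#' Describes the enclosure as an axis-aligned box: x runs along the long
#' (270 cm) wall, y along the short (150 cm) wall, z is vertical, origin at a
#' floor corner. A perch band at a fixed height runs along the walls and is
#' used by the synthetic generator's wall-attachment behavior.
#'
#' @slot lengthCm extent along the long wall (cm).
#' @slot widthCm extent along the short wall (cm).
#' @slot heightCm vertical extent (cm).
#' @slot perchHeightCm height of the perch band (cm), below heightCm.
#' @export
setClass("CageGeometry",
  representation(lengthCm = "numeric", widthCm = "numeric",
                 heightCm = "numeric", perchHeightCm = "numeric"),
  prototype(lengthCm = 270, widthCm = 150, heightCm = 200,
            perchHeightCm = 90))

setValidity("CageGeometry", function(object) {
  msg <- character()
  for (s in c("lengthCm", "widthCm", "heightCm", "perchHeightCm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  if (length(msg) == 0L && object@perchHeightCm >= object@heightCm)
    msg <- c(msg, "perchHeightCm must be below heightCm")
  if (length(msg)) msg else TRUE
})

#' Individual spatial footprint specification
#'
#' Parameters of one individual's stationary occupancy pattern used by the
#' synthetic generator: a preferred position, a positional dispersion around
#' it, and the fraction of time spent attached to the nearest wall (on the
#' perch band).
#'
#' @slot individualId individual label.
#' @slot centerCm length-3 preferred position (x, y, z) in cm.
#' @slot spreadCm length-3 positional dispersion (stationary SD, cm).
#' @slot wallAffinity fraction in [0, 1] of time biased toward the nearest
#'   wall band.
#' @export
setClass("FootprintSpec",
  representation(individualId = "character", centerCm = "numeric",
                 spreadCm = "numeric", wallAffinity = "numeric"))

setValidity("FootprintSpec", function(object) {
  msg <- character()
  if (length(object@individualId) != 1L || !nzchar(object@individualId))
    msg <- c(msg, "individualId must be a single non-empty label")
  if (length(object@centerCm) != 3L || any(!is.finite(object@centerCm)))
    msg <- c(msg, "centerCm must be a finite length-3 vector")
  if (length(object@spreadCm) != 3L || any(!is.finite(object@spreadCm)) ||
      any(object@spreadCm <= 0))
    msg <- c(msg, "spreadCm must be a positive length-3 vector")
  if (length(object@wallAffinity) != 1L || !is.finite(object@wallAffinity) ||
      object@wallAffinity < 0 || object@wallAffinity > 1)
    msg <- c(msg, "wallAffinity must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pairwise social attraction specification
#'
#' A symmetric matrix of stay-together probabilities: whenever a pair's
#' distance drops below \code{closeThreshCm}, at each subsequent tick the pair
#' keeps (freezes) both positions with the given probability, producing the
#' close-proximity mode of bimodal interpersonal-distance distributions.
#'
#' @slot pStay symmetric numeric matrix with zero diagonal, entries in [0, 1],
#'   dimnames = individual labels.
#' @slot closeThreshCm distance (cm) below which the stay rule applies.
#' @export
setClass("SocialSpec",
  representation(pStay = "matrix", closeThreshCm = "numeric"))

setValidity("SocialSpec", function(object) {
  msg <- character()
  p <- object@pStay
  if (!is.numeric(p) || nrow(p) != ncol(p))
    msg <- c(msg, "pStay must be a square numeric matrix")
  else {
    if (is.null(rownames(p)) || !identical(rownames(p), colnames(p)))
      msg <- c(msg, "pStay must have matching row/col individual labels")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      msg <- c(msg, "pStay entries must be in [0, 1]")
    if (!isTRUE(all.equal(p, t(p))))
      msg <- c(msg, "pStay must be symmetric")
    if (any(diag(p) != 0))
      msg <- c(msg, "pStay diagonal must be zero")
  }
  if (length(object@closeThreshCm) != 1L || object@closeThreshCm <= 0)
    msg <- c(msg, "closeThreshCm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Session specification
#'
#' @slot roster ordered individual labels present in the session (3 or 4 in
#'   the study design; any size >= 1 is accepted).
#' @slot durationS session length in seconds.
#' @slot rateHz sampling rate (Hz).
#' @slot missingRate per-sample probability that an individual's position is
#'   dropped (occlusion), in [0, 1).
#' @slot seed integer random seed for the session.
#' @export
setClass("SessionSpec",
  representation(roster = "character", durationS = "numeric",
                 rateHz = "numeric", missingRate = "numeric",
                 seed = "integer"))

setValidity("SessionSpec", function(object) {
  msg <- character()
  if (anyDuplicated(object@roster))
    msg <- c(msg, "roster must not contain duplicates")
  if (length(object@roster) < 1L)
    msg <- c(msg, "roster must contain at least one individual")
  if (length(object@durationS) != 1L || object@durationS < 0)
    msg <- c(msg, "durationS must be a single non-negative number")
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (length(object@missingRate) != 1L || object@missingRate < 0 ||
      object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Time-aligned multi-individual 3D trajectories for one session
#'
#' All individuals share one time base at a fixed sampling rate. Positions are
#' stored per individual as an n x 3 matrix (columns x_cm, y_cm, z_cm); a row
#' of NA marks a missing (occluded) sample. Non-missing positions always lie
#' inside the cage box.
#'
#' @slot sessionId session label.
#' @slot roster ordered individual labels.
#' @slot rateHz sampling rate (Hz).
#' @slot timesS sample times (s), strictly increasing with spacing 1/rateHz.
#' @slot positions named list (one per roster member) of n x 3 matrices.
#' @slot geometry the \linkS4class{CageGeometry} the positions live in.
#' @export
setClass("TrajectorySet",
  representation(sessionId = "character", roster = "character",
                 rateHz = "numeric", timesS = "numeric",
                 positions = "list", geometry = "CageGeometry"))

setValidity("TrajectorySet", function(object) {
  msg <- character()
  n <- length(object@timesS)
  if (!identical(names(object@positions), object@roster))
    msg <- c(msg, "positions must be named exactly by the roster, in order")
  if (n > 1L) {
    dt <- diff(object@timesS)
    if (any(dt <= 0))
      msg <- c(msg, "timesS must be strictly increasing")
    else if (any(abs(dt - 1 / object@rateHz) > 1e-6))
      msg <- c(msg, "timesS spacing must equal 1/rateHz")
  }
  box <- c(object@geometry@lengthCm, object@geometry@widthCm,
           object@geometry@heightCm)
  for (id in names(object@positions)) {
    p <- object@positions[[id]]
    if (!is.matrix(p) || ncol(p) != 3L || nrow(p) != n) {
      msg <- c(msg, sprintf("positions[['%s']] must be a %d x 3 matrix", id, n))
      next
    }
    ok <- stats::complete.cases(p)
    if (any(ok)) {
      q <- p[ok, , drop = FALSE]
      if (any(q < -1e-9) || any(q > rep(box, each = nrow(q)) + 1e-9))
        msg <- c(msg, sprintf("positions[['%s']] fall outside the cage box", id))
    }
    # a partially missing row is not allowed: a sample is tracked or not
    bad <- !ok & rowSums(is.na(p)) < 3L
    if (any(bad))
      msg <- c(msg, sprintf("positions[['%s']] has partially-NA rows", id))
  }
  if (length(msg)) msg else TRUE
})

#' Normalized occupancy map
#'
#' Fraction of session time an individual spends in each cell of a horizontal
#' grid over the cage floor plan: 16 bins along the short (150 cm, y) axis by
#' 29 bins along the long (270 cm, x) axis by default, each cell about 9.3 cm.
#' Entries are non-negative and sum to 1 when any non-missing sample exists.
#'
#' @slot individualId individual label.
#' @slot sessionId session label.
#' @slot grid nYBins x nXBins matrix of time fractions.
#' @slot xEdges bin edges along the long axis (cm).
#' @slot yEdges bin edges along the short axis (cm).
#' @export
setClass("OccupancyMap",
  representation(individualId = "character", sessionId = "character",
                 grid = "matrix", xEdges = "numeric", yEdges = "numeric"))

setValidity("OccupancyMap", function(object) {
  msg <- character()
  g <- object@grid
  if (any(g < 0)) msg <- c(msg, "grid entries must be non-negative")
  s <- sum(g)
  if (s > 0 && abs(s - 1) > 1e-9)
    msg <- c(msg, "grid must sum to 1")
  if (length(object@xEdges) != ncol(g) + 1L ||
      length(object@yEdges) != nrow(g) + 1L)
    msg <- c(msg, "bin edges inconsistent with grid dimensions")
  if (length(msg)) msg else TRUE
})

#' Per-pair interpersonal distance series
#'
#' Euclidean 3D distance between two individuals at every tick where both are
#' tracked; original tick indices are retained so run/bout structure is
#' recoverable.
#'
#' @slot pair the two individual labels.
#' @slot ticks retained tick indices (1-based, strictly increasing).
#' @slot dCm per-tick distance (cm).
#' @slot rateHz sampling rate (Hz).
#' @export
setClass("DistanceSeries",
  representation(pair = "character", ticks = "integer", dCm = "numeric",
                 rateHz = "numeric"))

setValidity("DistanceSeries", function(object) {
  msg <- character()
  if (length(object@pair) != 2L)
    msg <- c(msg, "pair must contain exactly two labels")
  if (length(object@ticks) != length(object@dCm))
    msg <- c(msg, "ticks and dCm must have equal length")
  if (length(object@ticks) > 1L && any(diff(object@ticks) <= 0))
    msg <- c(msg, "ticks must be strictly increasing")
  if (any(object@dCm < 0))
    msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Close-proximity bout (chunk) durations for a pair
#'
#' Maximal runs of consecutive ticks during which the pair's distance stays
#' below a threshold; a single below-threshold sample counts as a one-sample
#' chunk. Durations are in seconds (run length / sampling rate).
#'
#' @slot pair the two individual labels.
#' @slot durationsS bout durations (s), each > 0.
#' @slot thresholdCm distance threshold (cm).
#' @slot rateHz sampling rate (Hz).
#' @export
setClass("ChunkSet",
  representation(pair = "character", durationsS = "numeric",
                 thresholdCm = "numeric", rateHz = "numeric"))

setValidity("ChunkSet", function(object) {
  if (any(object@durationsS <= 0)) "durations must be positive" else TRUE
})

#' Decoding result for one pair and protocol
#'
#' @slot pair the two individual labels.
#' @slot protocol "within_cv", "cross_session" or "cross_context".
#' @slot accuracies per-fold (within_cv) or per-test-session accuracies.
#' @slot meanAccuracy mean of accuracies.
#' @slot nullAccuracies shuffled-label null accuracies.
#' @slot pValue (1 + #null >= observed) / (1 + #null).
#' @export
setClass("DecodingResult",
  representation(pair = "character", protocol = "character",
                 accuracies = "numeric", meanAccuracy = "numeric",
                 nullAccuracies = "numeric", pValue = "numeric"))

setValidity("DecodingResult", function(object) {
  msg <- character()
  acc <- c(object@accuracies, object@nullAccuracies)
  if (isTRUE(any(acc < 0 | acc > 1, na.rm = TRUE)))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  p <- object@pValue
  if (length(p) && isTRUE(any(p < 0 | p > 1, na.rm = TRUE)))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Resampled permutation-test result for the context-change index
#'
#' @slot meanP average p value over repeats (the inference quantity).
#' @slot tValues per-repeat t statistics.
#' @slot pValues per-repeat p values.
#' @slot nRepeats number of resampling repeats.
#' @slot nPerGroup values drawn (with replacement) per group per repeat.
#' @export
setClass("PermutationTestResult",
  representation(meanP = "numeric", tValues = "numeric", pValues = "numeric",
                 nRepeats = "integer", nPerGroup = "integer"))

setValidity("PermutationTestResult", function(object) {
  msg <- character()
  if (object@meanP < 0 || object@meanP > 1)
    msg <- c(msg, "meanP must lie in [0, 1]")
  if (length(object@tValues) != object@nRepeats)
    msg <- c(msg, "tValues length must equal nRepeats")
  if (length(msg)) msg else TRUE
})

#' Configuration of the two-agent lattice random walk
#'
#' A 240 x 140 step lattice; agents are confined to the band of points within
#' \code{wallMargin} units of the nearest boundary (the perch frame). At each
#' sample each agent draws a uniform direction and an integer step length in
#' [stepMin, stepMax]; moves leaving the band are re-drawn. Once the agents'
#' distance drops below \code{proximityThresh}, with probability \code{pStay}
#' both keep their positions at the next sample.
#'
#' @slot gridX,gridY lattice extents (steps).
#' @slot wallMargin width of the allowed wall band (steps).
#' @slot stepMin,stepMax integer step-length range.
#' @slot nSamples number of samples to simulate.
#' @slot proximityThresh distance below which the stay rule applies.
#' @slot pStay stay-together probability in [0, 1].
#' @slot seed integer random seed.
#' @export
setClass("WalkConfig",
  representation(gridX = "integer", gridY = "integer", wallMargin = "integer",
                 stepMin = "integer", stepMax = "integer",
                 nSamples = "integer", proximityThresh = "numeric",
                 pStay = "numeric", seed = "integer"),
  prototype(gridX = 240L, gridY = 140L, wallMargin = 40L, stepMin = 1L,
            stepMax = 40L, nSamples = 10000L, proximityThresh = 10,
            pStay = 0, seed = 1L))

setValidity("WalkConfig", function(object) {
  msg <- character()
  if (object@pStay < 0 || object@pStay > 1)
    msg <- c(msg, "pStay must lie in [0, 1]")
  if (object@stepMin < 1L || object@stepMax < object@stepMin)
    msg <- c(msg, "require 1 <= stepMin <= stepMax")
  if (object@wallMargin >= min(object@gridX, object@gridY) / 2)
    msg <- c(msg, "wallMargin must be below half the smaller grid extent")
  if (object@nSamples <= 0L)
    msg <- c(msg, "nSamples must be positive")
  if (length(msg)) msg else TRUE
})

#' Result of a two-agent lattice walk simulation
#'
#' @slot positionsA,positionsB nSamples x 2 matrices of lattice coordinates.
#' @slot distance per-sample Euclidean distance between agents.
#' @slot closeFraction fraction of samples with distance < proximityThresh.
#' @slot config the \linkS4class{WalkConfig} used.
#' @export
setClass("WalkResult",
  representation(positionsA = "matrix", positionsB = "matrix",
                 distance = "numeric", closeFraction = "numeric",
                 config = "WalkConfig"))

setValidity("WalkResult", function(object) {
  msg <- character()
  if (any(object@distance < 0)) msg <- c(msg, "distances must be non-negative")
  if (nrow(object@positionsA) != length(object@distance) ||
      nrow(object@positionsB) != length(object@distance))
    msg <- c(msg, "positions and distance must have matching length")
  if (length(msg)) msg else TRUE
})
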