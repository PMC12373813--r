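#' Construct a cage geometry
#'
#' Defaults describe the study enclosure: a 270 x 150 cm floor plan, 200 cm
#' high, with a perch band at 90 cm running along the walls.
#'
#' @param lengthCm,widthCm,heightCm box extents in cm.
#' @param perchHeightCm perch band height in cm.
#' @return A \linkS4class{CageGeometry}.
#' @examples
#' cageGeometry()
#' @export
cageGeometry <- function(lengthCm = 270, widthCm = 150, heightCm = 200,
                         perchHeightCm = 90) {
  new("CageGeometry", lengthCm = lengthCm, widthCm = widthCm,
      heightCm = heightCm, perchHeightCm = perchHeightCm)
}

#' Construct an individual footprint specification
#'
#' @param individualId individual label.
#' @param centerCm length-3 preferred position (x, y, z) in cm.
#' @param spreadCm positional dispersion (stationary SD, cm); scalar values
#'   are recycled to length 3.
#' @param wallAffinity fraction of time in the wall-attached (perch) state.
#' @param geometry optional \linkS4class{CageGeometry}; when supplied, the
#'   center is checked to lie inside the cage.
#' @return A \linkS4class{FootprintSpec}.
#' @export
footprintSpec <- function(individualId, centerCm, spreadCm = c(20, 20, 20),
                          wallAffinity = 0.5, geometry = NULL) {
  if (length(spreadCm) == 1L) spreadCm <- rep(spreadCm, 3L)
  obj <- new("FootprintSpec", individualId = as.character(individualId),
             centerCm = as.numeric(centerCm), spreadCm = as.numeric(spreadCm),
             wallAffinity = wallAffinity)
  if (!is.null(geometry)) {
    box <- c(geometry@lengthCm, geometry@widthCm, geometry@heightCm)
    if (any(obj@centerCm < 0) || any(obj@centerCm > box))
      stop("footprint center for '", individualId,
           "' lies outside the cage box", call. = FALSE)
  }
  obj
}

#' Construct a social attraction specification
#'
#' @param roster individual labels (order fixes the matrix indexing).
#' @param pStay either a symmetric matrix of stay-together probabilities
#'   (dimnames optional, taken from roster) or a single number applied to
#'   every pair; diagonal forced to zero.
#' @param closeThreshCm distance (cm) below which the stay rule applies.
#' @return A \linkS4class{SocialSpec}.
#' @export
socialSpec <- function(roster, pStay = 0, closeThreshCm = 50) {
  k <- length(roster)
  if (is.matrix(pStay)) {
    m <- pStay
    if (nrow(m) != k || ncol(m) != k)
      stop("pStay matrix must be ", k, " x ", k, call. = FALSE)
  } else {
    m <- matrix(as.numeric(pStay), k, k)
  }
  dimnames(m) <- list(roster, roster)
  diag(m) <- 0
  new("SocialSpec", pStay = m, closeThreshCm = closeThreshCm)
}

#' Construct a session specification
#'
#' @param roster ordered individual labels present in the session.
#' @param durationS session length in seconds (study sessions: 3 h; the
#'   package's demo scale uses shorter sessions).
#' @param rateHz sampling rate (default 15 Hz, the tracking rate).
#' @param missingRate per-sample occlusion probability (default 0.05).
#' @param seed integer random seed.
#' @return A \linkS4class{SessionSpec}.
#' @export
sessionSpec <- function(roster, durationS, rateHz = 15, missingRate = 0.05,
                        seed = 1L) {
  new("SessionSpec", roster = as.character(roster),
      durationS = as.numeric(durationS), rateHz = as.numeric(rateHz),
      missingRate = as.numeric(missingRate), seed = as.integer(seed))
}

#' Construct a trajectory set
#'
#' Low-level constructor; most users obtain trajectory sets from
#' \code{\link{generateSession}} or \code{\link{readSession}}.
#'
#' @param sessionId session label.
#' @param roster ordered individual labels.
#' @param rateHz sampling rate (Hz).
#' @param positions named list of n x 3 position matrices (NA row = missing).
#' @param geometry a \linkS4class{CageGeometry}.
#' @param timesS optional explicit time base; defaults to (0:(n-1))/rateHz.
#' @return A \linkS4class{TrajectorySet}.
#' @export
trajectorySet <- function(sessionId, roster, rateHz, positions,
                          geometry = cageGeometry(), timesS = NULL) {
  n <- if (length(positions)) nrow(positions[[1L]]) else 0L
  if (is.null(timesS)) timesS <- seq_len(n) / rateHz - 1 / rateHz
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x_cm", "y_cm", "z_cm")
    p
  })
  names(positions) <- roster
  new("TrajectorySet", sessionId = as.character(sessionId),
      roster = as.character(roster), rateHz = rateHz,
      timesS = as.numeric(timesS), positions = positions,
      geometry = geometry)
}

#' Construct a walk configuration
#'
#' Defaults are the mechanistic model's standard settings: a 240 x 140 step
#' lattice, a 40-unit wall band, uniform integer steps in [1, 40], 1e4
#' samples, close-proximity threshold 10 units.
#'
#' @param pStay stay-together probability in [0, 1].
#' @param seed integer random seed.
#' @param gridX,gridY lattice extents (steps).
#' @param wallMargin wall-band width (steps).
#' @param stepMin,stepMax integer step-length range.
#' @param nSamples number of samples.
#' @param proximityThresh close-proximity threshold (lattice units).
#' @return A \linkS4class{WalkConfig}.
#' @examples
#' walkConfig(pStay = 0.5, seed = 7L)
#' @export
walkConfig <- function(pStay = 0, seed = 1L, gridX = 240L, gridY = 140L,
                       wallMargin = 40L, stepMin = 1L, stepMax = 40L,
                       nSamples = 10000L, proximityThresh = 10) {
  new("WalkConfig", gridX = as.integer(gridX), gridY = as.integer(gridY),
      wallMargin = as.integer(wallMargin), stepMin = as.integer(stepMin),
      stepMax = as.integer(stepMax), nSamples = as.integer(nSamples),
      proximityThresh = as.numeric(proximityThresh),
      pStay = as.numeric(pStay), seed = as.integer(seed))
}
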