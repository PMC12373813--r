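## Synthetic multi-individual trajectory sessions.
##
## The generator's job is to reproduce the statistical structure the
## downstream analyses consume -- stationary, individual-specific,
## wall-attached occupancy plus pairwise attraction -- not real macaque
## kinematics. Each individual follows a discrete-time mean-reverting
## (AR(1)) walk toward an attractor that alternates between the footprint
## center and its projection onto the nearest wall at perch height, with
## reflection at the cage walls. Pairs already in close proximity freeze
## both positions for one tick with probability pStay.

reflectIntoBox <- function(p, box) {
  # fold coordinates back into [0, box] (repeated reflection)
  for (j in 1:3) {
    v <- p[, j]
    for (it in 1:50) {
      bad <- v < 0 | v > box[j]
      if (!any(bad)) break
      v <- ifelse(v < 0, -v, v)
      v <- ifelse(v > box[j], 2 * box[j] - v, v)
    }
    p[, j] <- pmin(pmax(v, 0), box[j])
  }
  p
}

wallTarget <- function(center, geom) {
  # attractor in the wall-attached state: center projected to the nearest
  # vertical wall (5 cm standoff), raised to perch height
  dWalls <- c(center[1], geom@lengthCm - center[1],
              center[2], geom@widthCm - center[2])
  w <- which.min(dWalls)
  tgt <- center
  if (w == 1L) tgt[1] <- 5
  else if (w == 2L) tgt[1] <- geom@lengthCm - 5
  else if (w == 3L) tgt[2] <- 5
  else tgt[2] <- geom@widthCm - 5
  tgt[3] <- geom@perchHeightCm
  tgt
}

simulateWallState <- function(n, wallAffinity, rateHz, cycleS = 60) {
  # two-state (wall / center) Markov chain with stationary wall fraction
  # wallAffinity and a mean full cycle of about cycleS seconds
  if (wallAffinity <= 0) return(rep(FALSE, n))
  if (wallAffinity >= 1) return(rep(TRUE, n))
  dwellWall <- max(1, wallAffinity * cycleS * rateHz)
  dwellCenter <- max(1, (1 - wallAffinity) * cycleS * rateHz)
  pLeaveWall <- 1 / dwellWall
  pLeaveCenter <- 1 / dwellCenter
  state <- logical(n)
  state[1L] <- stats::runif(1) < wallAffinity
  if (n > 1L) {
    u <- stats::runif(n - 1L)
    for (t in 2:n) {
      state[t] <- if (state[t - 1L]) u[t - 1L] >= pLeaveWall
                  else u[t - 1L] < pLeaveCenter
    }
  }
  state
}

#' Generate one synthetic multi-individual session
#'
#' Simulates time-aligned 3D positions for every roster member: each
#' individual performs a mean-reverting random walk around its footprint
#' center (alternating with a wall-attached state at perch height according
#' to its wall affinity), positions are reflected at the cage walls, and
#' pairs closer than the social close threshold freeze both positions for
#' one tick with their stay-together probability. Samples are then dropped
#' independently at the session's missing rate to emulate occlusion gaps.
#'
#' Output is bit-reproducible for a fixed \code{spec} seed.
#'
#' @param geometry a \linkS4class{CageGeometry}.
#' @param footprints list of \linkS4class{FootprintSpec}, one per roster
#'   member (extra footprints are ignored).
#' @param social a \linkS4class{SocialSpec} whose matrix covers the roster.
#' @param spec a \linkS4class{SessionSpec}.
#' @param sessionId session label (default derived from the seed).
#' @return A \linkS4class{TrajectorySet}.
#' @examples
#' geom <- cageGeometry()
#' fp <- list(footprintSpec("a", c(60, 40, 90)),
#'            footprintSpec("b", c(220, 110, 90)))
#' soc <- socialSpec(c("a", "b"), pStay = 0.3)
#' ts <- generateSession(geom, fp, soc, sessionSpec(c("a", "b"), 60, seed = 1))
#' ts
#' @export
generateSession <- function(geometry, footprints, social, spec,
                            sessionId = sprintf("S%05d", spec@seed)) {
  stopifnot(is(geometry, "CageGeometry"), is(social, "SocialSpec"),
            is(spec, "SessionSpec"))
  validObject(spec)
  fpIds <- vapply(footprints, function(f) f@individualId, character(1))
  missing <- setdiff(spec@roster, fpIds)
  if (length(missing))
    stop("no FootprintSpec for roster member(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(spec@roster %in% rownames(social@pStay)))
    stop("social pStay matrix does not cover the roster", call. = FALSE)
  box <- c(geometry@lengthCm, geometry@widthCm, geometry@heightCm)
  fps <- footprints[match(spec@roster, fpIds)]
  for (f in fps) {
    if (any(f@centerCm < 0) || any(f@centerCm > box))
      stop("footprint center for '", f@individualId,
           "' lies outside the cage box", call. = FALSE)
  }

  k <- length(spec@roster)
  n <- as.integer(round(spec@durationS * spec@rateHz))
  if (n == 0L) {
    empty <- replicate(k, matrix(numeric(0), 0, 3), simplify = FALSE)
    return(trajectorySet(sessionId, spec@roster, spec@rateHz, empty,
                         geometry))
  }

  set.seed(spec@seed)
  # AR(1) mean reversion with ~2 s relaxation time; innovation SD chosen so
  # the stationary SD equals the requested spread
  phi <- exp(-1 / (2 * spec@rateHz))
  centers <- t(vapply(fps, function(f) f@centerCm, numeric(3)))
  spreads <- t(vapply(fps, function(f) f@spreadCm, numeric(3)))
  wallTgts <- t(vapply(fps, function(f) wallTarget(f@centerCm, geometry),
                       numeric(3)))
  sdEps <- spreads * sqrt(1 - phi^2)

  wallState <- matrix(FALSE, n, k)
  for (i in seq_len(k))
    wallState[, i] <- simulateWallState(n, fps[[i]]@wallAffinity,
                                        spec@rateHz)
  eps <- array(stats::rnorm(n * k * 3), dim = c(n, k, 3))

  pS <- social@pStay[spec@roster, spec@roster, drop = FALSE]
  anySocial <- any(pS > 0)
  pairIdx <- if (k >= 2) utils::combn(k, 2) else matrix(integer(0), 2, 0)

  pos <- array(NA_real_, dim = c(n, k, 3))
  # start at the stationary distribution around the center attractor
  cur <- centers + matrix(stats::rnorm(k * 3), k, 3) * spreads
  cur <- reflectIntoBox(cur, box)
  pos[1L, , ] <- cur

  for (t in seq_len(n - 1L)) {
    tgt <- centers
    w <- wallState[t + 1L, ]
    if (any(w)) tgt[w, ] <- wallTgts[w, , drop = FALSE]
    prop <- tgt + phi * (cur - tgt) +
      matrix(eps[t + 1L, , ], k, 3) * sdEps
    prop <- reflectIntoBox(prop, box)
    if (anySocial && ncol(pairIdx)) {
      frozen <- logical(k)
      for (c in seq_len(ncol(pairIdx))) {
        i <- pairIdx[1L, c]; j <- pairIdx[2L, c]
        p <- pS[i, j]
        if (p > 0 && sqrt(sum((cur[i, ] - cur[j, ])^2)) <
            social@closeThreshCm) {
          if (stats::runif(1) < p) frozen[i] <- frozen[j] <- TRUE
        }
      }
      if (any(frozen)) prop[frozen, ] <- cur[frozen, , drop = FALSE]
    }
    cur <- prop
    pos[t + 1L, , ] <- cur
  }

  positions <- vector("list", k)
  for (i in seq_len(k)) {
    m <- pos[, i, ]
    if (spec@missingRate > 0) {
      drop <- stats::runif(n) < spec@missingRate
      m[drop, ] <- NA_real_
    }
    positions[[i]] <- m
  }
  names(positions) <- spec@roster
  trajectorySet(sessionId, spec@roster, spec@rateHz, positions, geometry)
}

#' Generate a full study's worth of sessions
#'
#' Produces \code{nQuadruple} sessions with the full roster and, for each
#' named removal in \code{tripletPlan}, that many triplet sessions with the
#' named individual absent (the study design: 19 quadruple days plus 10
#' triplet sessions over 4 removal kinds). Per-session seeds are derived as
#' \code{baseSeed + session index}, so the collection is deterministic given
#' \code{baseSeed}.
#'
#' @param geometry a \linkS4class{CageGeometry}.
#' @param footprints list of \linkS4class{FootprintSpec} covering the full
#'   roster (their order defines the full roster).
#' @param social a \linkS4class{SocialSpec} covering the full roster.
#' @param nQuadruple number of full-roster sessions (>= 0).
#' @param tripletPlan named integer vector: names are removed individuals,
#'   values the number of sessions without them (possibly empty).
#' @param baseSeed integer master seed.
#' @param durationS per-session length in seconds (default 600, the
#'   package's demo scale; the study's sessions were 3 h).
#' @param rateHz sampling rate (default 15).
#' @param missingRate per-sample occlusion probability (default 0.05).
#' @return Named list of \linkS4class{TrajectorySet} (quadruples first).
#' @export
generateStudy <- function(geometry, footprints, social, nQuadruple,
                          tripletPlan = integer(0), baseSeed = 1L,
                          durationS = 600, rateHz = 15,
                          missingRate = 0.05) {
  stopifnot(nQuadruple >= 0, all(tripletPlan >= 0))
  fullRoster <- vapply(footprints, function(f) f@individualId, character(1))
  if (length(tripletPlan)) {
    bad <- setdiff(names(tripletPlan), fullRoster)
    if (length(bad))
      stop("tripletPlan removes unknown individual(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  sessions <- list()
  idx <- 0L
  for (q in seq_len(nQuadruple)) {
    idx <- idx + 1L
    id <- sprintf("quad%02d", q)
    sp <- sessionSpec(fullRoster, durationS, rateHz, missingRate,
                      seed = baseSeed + idx)
    sessions[[id]] <- generateSession(geometry, footprints, social, sp,
                                      sessionId = id)
  }
  for (rm in names(tripletPlan)) {
    for (r in seq_len(tripletPlan[[rm]])) {
      idx <- idx + 1L
      id <- sprintf("trip_%s_%02d", rm, r)
      sp <- sessionSpec(setdiff(fullRoster, rm), durationS, rateHz,
                        missingRate, seed = baseSeed + idx)
      sessions[[id]] <- generateSession(geometry, footprints, social, sp,
                                        sessionId = id)
    }
  }
  sessions
}

#' Default four-individual study setup
#'
#' A convenience bundle of geometry, footprints and social structure used in
#' examples, tests and the demo pipeline: four individuals with distinct
#' preferred locations spread around the cage (pairwise well over 100 cm
#' apart), 20 cm spread, moderate wall affinity, and one affiliated pair
#' ("m1"-"m2") with a stay-together probability of 0.6 within 50 cm.
#'
#' @param pStayAffiliated stay probability for the affiliated pair.
#' @return List with elements \code{geometry}, \code{footprints},
#'   \code{social}, \code{roster}.
#' @export
defaultStudySetup <- function(pStayAffiliated = 0.6) {
  geom <- cageGeometry()
  roster <- c("m1", "m2", "m3", "m4")
  fps <- list(
    footprintSpec("m1", c(40, 30, 90), 20, wallAffinity = 0.6, geom),
    footprintSpec("m2", c(70, 130, 120), 20, wallAffinity = 0.6, geom),
    footprintSpec("m3", c(230, 120, 120), 20, wallAffinity = 0.6, geom),
    footprintSpec("m4", c(220, 20, 60), 20, wallAffinity = 0.6, geom))
  p <- matrix(0, 4, 4, dimnames = list(roster, roster))
  p["m1", "m2"] <- p["m2", "m1"] <- pStayAffiliated
  soc <- new("SocialSpec", pStay = p, closeThreshCm = 50)
  list(geometry = geom, footprints = fps, social = soc, roster = roster)
}
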