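# Shared fixtures, all generated in code.

# trajectory set built directly from position matrices (no simulation)
makeTrajectory <- function(positions, rateHz = 15, sessionId = "fix",
                           geometry = cageGeometry()) {
  trajectorySet(sessionId, names(positions), rateHz, positions, geometry)
}

# constant-position trajectory for each individual
constantTrajectory <- function(coords, n, rateHz = 15, sessionId = "fix") {
  pos <- lapply(coords, function(p) matrix(rep(p, each = n), n, 3))
  makeTrajectory(pos, rateHz = rateHz, sessionId = sessionId)
}

# random normalized occupancy grid
randomMap <- function(individual = "m1", session = "s", nY = 16, nX = 29) {
  g <- matrix(stats::rexp(nY * nX), nY, nX)
  g <- g / sum(g)
  new("OccupancyMap", individualId = individual, sessionId = session,
      grid = g, xEdges = seq(0, 270, length.out = nX + 1),
      yEdges = seq(0, 150, length.out = nY + 1))
}

# distance series built directly from values
makeSeries <- function(d, ticks = seq_along(d), pair = c("a", "b"),
                       rateHz = 15) {
  new("DistanceSeries", pair = pair, ticks = as.integer(ticks),
      dCm = as.numeric(d), rateHz = rateHz)
}

# small multi-session synthetic study (cached per test file)
smallStudy <- local({
  cache <- NULL
  function(nQuadruple = 3, tripletPlan = c(m3 = 1), durationS = 30,
           seed = 404) {
    key <- paste(nQuadruple, paste(names(tripletPlan), tripletPlan,
                                   collapse = "+"), durationS, seed)
    if (!is.null(cache) && identical(attr(cache, "key"), key))
      return(cache)
    setup <- defaultStudySetup()
    out <- generateStudy(setup$geometry, setup$footprints, setup$social,
                         nQuadruple, tripletPlan, baseSeed = seed,
                         durationS = durationS)
    attr(out, "key") <- key
    cache <<- out
    out
  }
})
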