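test_that("distance series match the per-sample Euclidean norm", {
  ts <- makeTrajectory(list(a = matrix(c(0, 0, 0), 1, 3, byrow = TRUE),
                            b = matrix(c(3, 4, 0), 1, 3, byrow = TRUE)))
  expect_equal(distances(distanceSeries(ts, "a", "b")), 5)

  same <- constantTrajectory(list(a = c(9, 9, 9), b = c(9, 9, 9)), n = 4)
  expect_equal(distances(distanceSeries(same, "a", "b")), rep(0, 4))

  set.seed(61)
  n <- 200
  pos <- list(a = cbind(runif(n, 0, 270), runif(n, 0, 150), runif(n, 0, 200)),
              b = cbind(runif(n, 0, 270), runif(n, 0, 150), runif(n, 0, 200)))
  rts <- makeTrajectory(pos)
  d <- distances(distanceSeries(rts, "a", "b"))
  oracle <- vapply(seq_len(n), function(i)
    sqrt(sum((pos$a[i, ] - pos$b[i, ])^2)), numeric(1))
  expect_equal(d, oracle, tolerance = 1e-12)
  # symmetry
  expect_identical(d, distances(distanceSeries(rts, "b", "a")))
  expect_error(distanceSeries(rts, "a", "a"), "distinct")
})

test_that("mean distance matrix averages sessions and flags absent pairs", {
  s1 <- constantTrajectory(list(a = c(10, 10, 10), b = c(110, 10, 10)),
                           n = 5, sessionId = "s1")
  s2 <- constantTrajectory(list(a = c(10, 10, 10), b = c(100, 10, 10)),
                           n = 5, sessionId = "s2")
  mdm <- meanDistanceMatrix(list(s1, s2))
  expect_equal(mdm$matrix["a", "b"], 95)   # mean of 100 and 90
  expect_true(is.na(mdm$matrix["a", "a"]))
})

test_that("pairwise attraction between rank-adjacent individuals orders mean distance", {
  geom <- cageGeometry()
  fps <- lapply(1:4, function(i)
    footprintSpec(paste0("r", i), c(70 + 40 * (i - 1), 75, 90), 35,
                  wallAffinity = 0))
  ros <- paste0("r", 1:4)
  p <- matrix(0, 4, 4, dimnames = list(ros, ros))
  for (i in 1:3) p[i, i + 1] <- p[i + 1, i] <- 0.8
  soc <- new("SocialSpec", pStay = p, closeThreshCm = 60)
  sessions <- lapply(1:3, function(k)
    generateSession(geom, fps, soc,
                    sessionSpec(ros, 300, missingRate = 0, seed = 70 + k),
                    sessionId = paste0("s", k)))
  mdm <- meanDistanceMatrix(sessions, rankOrder = ros)
  m <- mdm$matrix
  adj <- mean(c(m["r1", "r2"], m["r2", "r3"], m["r3", "r4"]))
  mid <- mean(c(m["r1", "r3"], m["r2", "r4"]))
  far <- m["r1", "r4"]
  expect_lt(adj, mid)
  expect_lt(mid, far)
})

test_that("distance distributions integrate to one and match known mixtures", {
  set.seed(71)
  n <- 1e5
  comp <- runif(n) < 0.3
  d <- ifelse(comp, rnorm(n, 40, 15), rnorm(n, 180, 40))
  d <- d[d >= 0 & d <= 368]
  dd <- distanceDistribution(d)
  expect_equal(sum(dd$raw), 1, tolerance = 1e-9)     # bin width 1 cm
  expect_equal(sum(dd$smooth), 1, tolerance = 1e-9)
  truth <- 0.3 * dnorm(dd$mid, 40, 15) + 0.7 * dnorm(dd$mid, 180, 40)
  truth <- truth / sum(truth)
  expect_lt(sum(abs(dd$raw - truth)), 0.1)

  spike <- distanceDistribution(rep(100, 2000))
  expect_identical(sum(spike$raw > 0), 1L)
  expect_error(distanceDistribution(numeric(0)), "empty")
})

test_that("threshold finder locates valleys and flags degenerate shapes", {
  set.seed(72)
  n <- 2e4
  comp <- runif(n) < 0.3
  d <- ifelse(comp, rnorm(n, 40, 15), rnorm(n, 180, 40))
  d <- d[d >= 0 & d <= 368]
  thr <- findAffiliationThresholds(distanceDistribution(d))
  expect_false(thr$unimodal)
  expect_lt(abs(thr$closeCm - 84.7), 3)  # smoothed-mixture valley
  expect_length(thr$modesCm, 2L)

  uni <- findAffiliationThresholds(
    distanceDistribution(pmax(pmin(rnorm(n, 150, 30), 368), 0)))
  expect_true(uni$unimodal)
  expect_true(is.na(uni$closeCm))

  # tri-modal: avoidance peak on the far right is reported, far threshold
  # sits after the central (main right-side) mode
  u <- runif(n)
  d3 <- ifelse(u < 0.25, rnorm(n, 40, 12),
               ifelse(u < 0.75, rnorm(n, 170, 25), rnorm(n, 300, 18)))
  d3 <- d3[d3 >= 0 & d3 <= 368]
  thr3 <- findAffiliationThresholds(distanceDistribution(d3))
  expect_length(thr3$modesCm, 3L)
  expect_gt(thr3$farCm, 170)
  expect_lt(thr3$farCm, 300)
})

test_that("affiliative strength and weakness count partner time", {
  # one partner within 10 cm, the others far, for a 60 s session
  n <- 900
  ts <- constantTrajectory(list(a = c(100, 70, 90), b = c(105, 70, 90),
                                c = c(250, 10, 10), d = c(10, 140, 190)),
                           n = n)
  expect_equal(affiliativeStrength(ts, "a", closeCm = 73), 60)
  expect_equal(affiliativeStrength(ts, "d", closeCm = 73), 0)

  # random-series counting oracle, per partner
  set.seed(73)
  m <- 300
  pos <- list(a = cbind(runif(m, 0, 270), runif(m, 0, 150), runif(m, 0, 200)),
              b = cbind(runif(m, 0, 270), runif(m, 0, 150), runif(m, 0, 200)),
              c = cbind(runif(m, 0, 270), runif(m, 0, 150), runif(m, 0, 200)))
  rts <- makeTrajectory(pos)
  manual <- 0
  for (p in c("b", "c")) {
    d <- sqrt(rowSums((pos$a - pos[[p]])^2))
    manual <- manual + sum(d < 73) / 15
  }
  expect_equal(affiliativeStrength(rts, "a", closeCm = 73), manual)
  manualW <- 0
  for (p in c("b", "c")) {
    d <- sqrt(rowSums((pos$a - pos[[p]])^2))
    manualW <- manualW + sum(d > 185) / 15
  }
  expect_equal(affiliativeWeakness(rts, "a", farCm = 185), manualW)
  expect_error(affiliativeStrength(rts, "zz"), "unknown individual")
})

test_that("proximity chunks are maximal runs, breaking at occlusions", {
  # mask [1,1,0,1] -> runs of 2 and 1 samples
  d <- c(10, 10, 80, 10)
  cs <- proximityChunks(makeSeries(d), thresholdCm = 50)
  expect_equal(chunkDurations(cs) * 15, c(2, 1))

  # all below threshold: one run of n
  csAll <- proximityChunks(makeSeries(rep(5, 12)), thresholdCm = 50)
  expect_equal(chunkDurations(csAll) * 15, 12)

  # a missing tick splits a run unless bridged
  gap <- makeSeries(rep(5, 6), ticks = c(1, 2, 3, 5, 6, 7))
  expect_equal(chunkDurations(proximityChunks(gap)) * 15, c(3, 3))
  expect_equal(chunkDurations(proximityChunks(gap, bridgeGapTicks = 1L)) * 15,
               6)

  # run-length-encoding oracle on random masks
  set.seed(74)
  for (i in 1:50) {
    mask <- runif(40) < 0.4
    d <- ifelse(mask, 10, 100)
    got <- chunkDurations(proximityChunks(makeSeries(d), 50)) * 15
    r <- rle(mask)
    want <- r$lengths[r$values]
    expect_equal(got, as.numeric(want))
  }
})

test_that("chunk time and affiliation time agree when thresholds coincide", {
  setup <- defaultStudySetup()
  ts <- generateSession(setup$geometry, setup$footprints, setup$social,
                        sessionSpec(setup$roster, 120, missingRate = 0,
                                    seed = 75))
  thr <- 73
  for (p in c("m2", "m3")) {
    ds <- distanceSeries(ts, "m1", p)
    chunkTime <- sum(chunkDurations(proximityChunks(ds, thr)))
    below <- sum(distances(ds) < thr) / rateHz(ts)
    expect_equal(chunkTime, below)
  }
})

test_that("chunk histograms and KS comparisons behave across regimes", {
  set.seed(76)
  mkChunks <- function(durS, pair) new("ChunkSet", pair = pair,
                                       durationsS = durS,
                                       thresholdCm = 50, rateHz = 15)
  # clearly different duration scales are detected
  a <- mkChunks(rgeom(1000, 0.5) / 15 + 1 / 15, c("a", "b"))
  b <- mkChunks(rgeom(1000, 0.05) / 15 + 1 / 15, c("c", "d"))
  out <- chunkHistogramsCompare(list(ab = a, cd = b))
  expect_lt(out$ks$p_value, 0.001)
  expect_identical(sort(unique(out$histograms$pair)), c("ab", "cd"))
  expect_identical(sum(out$histograms$count[out$histograms$pair == "ab"]),
                   1000L)

  # same-distribution chunks are rarely flagged (null calibration)
  rej <- replicate(100, {
    x <- mkChunks(rgeom(300, 0.3) / 15 + 1 / 15, c("a", "b"))
    y <- mkChunks(rgeom(300, 0.3) / 15 + 1 / 15, c("c", "d"))
    suppressWarnings(chunkHistogramsCompare(list(x = x, y = y)))$ks$p_value <
      0.05
  })
  expect_lte(mean(rej), 0.08)

  # degenerate single-chunk input: histograms ok, KS skipped with warning
  one <- mkChunks(0.5, c("e", "f"))
  expect_warning(res1 <- chunkHistogramsCompare(list(ab = a, ef = one)),
                 "skipped")
  expect_identical(nrow(res1$histograms), 40L)
  expect_null(res1$ks)

  # empty chunk sets are excluded with a warning
  none <- mkChunks(numeric(0), c("g", "h"))
  expect_warning(chunkHistogramsCompare(list(ab = a, cd = b, gh = none)),
                 "no chunks")
  expect_error(suppressWarnings(chunkHistogramsCompare(list(gh = none,
                                                            ab = a))),
               "at least two")
})
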