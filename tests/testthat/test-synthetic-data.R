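setup <- defaultStudySetup()

test_that("zero-duration session yields an empty trajectory set", {
  ts <- generateSession(setup$geometry, setup$footprints, setup$social,
                        sessionSpec(setup$roster, 0, seed = 1))
  expect_identical(nTicks(ts), 0L)
  expect_identical(roster(ts), setup$roster)
  expect_identical(nrow(positions(ts, "m1")), 0L)
})

test_that("generation is reproducible and respects the cage box", {
  sp <- sessionSpec(setup$roster, 60, seed = 99)
  a <- generateSession(setup$geometry, setup$footprints, setup$social, sp)
  b <- generateSession(setup$geometry, setup$footprints, setup$social, sp)
  expect_identical(positions(a), positions(b))
  box <- c(270, 150, 200)
  for (id in roster(a)) {
    p <- positions(a, id)
    p <- p[stats::complete.cases(p), ]
    expect_true(all(p >= 0 & p <= rep(box, each = nrow(p))))
  }
})

test_that("configuration errors are raised", {
  expect_error(
    generateSession(setup$geometry, setup$footprints[1:3], setup$social,
                    sessionSpec(setup$roster, 10, seed = 1)),
    "no FootprintSpec")
  expect_error(
    footprintSpec("x", c(300, 10, 10), geometry = setup$geometry),
    "outside the cage")
  badFp <- list(footprintSpec("m1", c(300, 10, 10)))
  expect_error(
    generateSession(setup$geometry, badFp, socialSpec("m1", 0),
                    sessionSpec("m1", 10, seed = 1)),
    "outside the cage")
})

test_that("individuals with identical footprints are statistically
           indistinguishable (KS on thinned marginals)", {
  fp1 <- setup$footprints[[1]]
  fps <- list(
    footprintSpec("a", fp1@centerCm, fp1@spreadCm, fp1@wallAffinity),
    footprintSpec("b", fp1@centerCm, fp1@spreadCm, fp1@wallAffinity))
  ts <- generateSession(setup$geometry, fps, socialSpec(c("a", "b"), 0),
                        sessionSpec(c("a", "b"), 1e5 / 15,
                                    missingRate = 0, seed = 11))
  # thin to ~3 relaxation times so the KS independence premise holds
  idx <- seq(1, 1e5, by = 100)
  pa <- positions(ts, "a")[idx, ]
  pb <- positions(ts, "b")[idx, ]
  for (j in 1:3) {
    p <- suppressWarnings(stats::ks.test(pa[, j], pb[, j]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("median positions track footprint centers", {
  fps <- list(
    footprintSpec("a", c(40, 30, 50), 20, wallAffinity = 0),
    footprintSpec("b", c(160, 30, 50), 20, wallAffinity = 0),
    footprintSpec("c", c(40, 130, 150), 20, wallAffinity = 0),
    footprintSpec("d", c(230, 120, 150), 20, wallAffinity = 0))
  ros <- c("a", "b", "c", "d")
  ts <- generateSession(setup$geometry, fps, socialSpec(ros, 0),
                        sessionSpec(ros, 600, missingRate = 0, seed = 12))
  for (i in seq_along(ros)) {
    p <- positions(ts, ros[i])
    med <- apply(p, 2, stats::median)
    expect_lt(sqrt(sum((med - fps[[i]]@centerCm)^2)), 15)
  }
})

test_that("stay-together attraction raises close-proximity time, monotonically", {
  fps <- list(footprintSpec("a", c(100, 70, 90), 25, wallAffinity = 0),
              footprintSpec("b", c(150, 80, 90), 25, wallAffinity = 0))
  ros <- c("a", "b")
  closeFrac <- vapply(c(0, 0.3, 0.6, 0.9), function(p) {
    ts <- generateSession(setup$geometry, fps, socialSpec(ros, p, 50),
                          sessionSpec(ros, 600, missingRate = 0,
                                      seed = 31))
    mean(distances(distanceSeries(ts, "a", "b")) < 50)
  }, numeric(1))
  expect_gt(closeFrac[4], closeFrac[1])
  expect_true(all(diff(closeFrac) >= 0))
})

test_that("missing-sample fraction matches the requested rate", {
  ts <- generateSession(setup$geometry, setup$footprints, setup$social,
                        sessionSpec(setup$roster, 1e4 / 15,
                                    missingRate = 0.1, seed = 8))
  for (id in roster(ts)) {
    frac <- mean(!stats::complete.cases(positions(ts, id)))
    expect_lt(abs(frac - 0.1), 0.02)
  }
})

test_that("generateStudy builds the requested session structure", {
  plan <- c(m1 = 1, m2 = 1, m3 = 2, m4 = 1)
  study <- generateStudy(setup$geometry, setup$footprints, setup$social,
                         nQuadruple = 19, tripletPlan = plan,
                         baseSeed = 5, durationS = 4)
  expect_length(study, 19 + 5)
  sizes <- vapply(study, function(s) length(roster(s)), integer(1))
  expect_identical(unname(sizes[1:19]), rep(4L, 19))
  expect_identical(unname(sizes[20:24]), rep(3L, 5))
  expect_false("m3" %in% roster(study[["trip_m3_01"]]))
  again <- generateStudy(setup$geometry, setup$footprints, setup$social,
                         nQuadruple = 19, tripletPlan = plan,
                         baseSeed = 5, durationS = 4)
  expect_identical(positions(study[["trip_m3_02"]]),
                   positions(again[["trip_m3_02"]]))
  expect_length(generateStudy(setup$geometry, setup$footprints,
                              setup$social, 0, integer(0)), 0L)
  expect_error(generateStudy(setup$geometry, setup$footprints,
                             setup$social, 1, c(zz = 1)),
               "unknown individual")
})
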