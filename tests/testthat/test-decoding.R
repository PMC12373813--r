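setup <- defaultStudySetup()

sessionFor <- local({
  cache <- list()
  function(seed, durationS = 600, setupArg = setup) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generateSession(
        setupArg$geometry, setupArg$footprints, setupArg$social,
        sessionSpec(setupArg$roster, durationS, seed = seed))
    }
    cache[[key]]
  }
})

test_that("pair classifier separates distant clouds and guards bad input", {
  set.seed(41)
  a <- cbind(rnorm(500, 30, 10), rnorm(500, 30, 10), rnorm(500, 50, 10))
  b <- cbind(rnorm(500, 230, 10), rnorm(500, 120, 10), rnorm(500, 50, 10))
  fit <- trainPairClassifier(a, b)
  trainAcc <- mean(c(as.character(predict(fit, a)) == "A",
                     as.character(predict(fit, b)) == "B"))
  expect_gt(trainAcc, 0.99)

  expect_error(trainPairClassifier(a[1:9, ], b), "at least 10")

  same <- matrix(5, 20, 3)
  expect_warning(fitMaj <- trainPairClassifier(same, same), "degenerate")
  expect_true(fitMaj$degenerate)
  expect_identical(unique(as.character(predict(fitMaj, same))), "A")
})

test_that("within-session CV decodes separable footprints well above chance", {
  ts <- sessionFor(42)
  res <- withinSessionCV(ts, c("m1", "m4"), nShuffles = 0, seed = 2)
  expect_length(accuracies(res), 10L)
  expect_gte(meanAccuracy(res), 0.8)
  # determinism under a fixed seed
  res2 <- withinSessionCV(ts, c("m1", "m4"), nShuffles = 0, seed = 2)
  expect_identical(accuracies(res), accuracies(res2))
  # too few samples is a validation error
  short <- generateSession(setup$geometry, setup$footprints, setup$social,
                           sessionSpec(setup$roster, 5, seed = 3))
  expect_error(withinSessionCV(short, c("m1", "m2")), "too few samples")
})

test_that("shuffled labels and identical footprints decode at chance", {
  # wallAffinity 0: the wall-attachment state dwells for ~1 min, so over a
  # 10-minute session two identical-spec individuals would differ by chance
  # in their realized wall time; the chance-level premise needs the fast-
  # mixing footprint alone
  fp <- setup$footprints[[1]]
  twin <- list(footprintSpec("a", fp@centerCm, fp@spreadCm, 0),
               footprintSpec("b", fp@centerCm, fp@spreadCm, 0))
  tsSame <- generateSession(setup$geometry, twin, socialSpec(c("a", "b"), 0),
                            sessionSpec(c("a", "b"), 3600, seed = 7))
  res <- withinSessionCV(tsSame, c("a", "b"), nShuffles = 20,
                         maxPerClass = 2000, seed = 5)
  expect_gt(meanAccuracy(res), 0.45)
  expect_lt(meanAccuracy(res), 0.55)
  expect_gt(mean(nullAccuracies(res)), 0.45)
  expect_lt(mean(nullAccuracies(res)), 0.55)
})

test_that("cross-session decoding transfers footprints and detects swaps", {
  train <- sessionFor(42)
  tests <- lapply(43:44, function(s) sessionFor(s))
  res <- crossSessionDecode(train, tests, c("m1", "m3"), nShuffles = 50,
                            seed = 6)
  expect_length(accuracies(res), 2L)
  thresh <- stats::quantile(nullAccuracies(res), 0.95)
  expect_true(all(accuracies(res) > thresh))
  expect_lt(pValue(res), 0.05)

  # swapping the pair's footprints inverts the decision rule
  swapped <- setup$footprints
  c1 <- swapped[[1]]@centerCm
  swapped[[1]]@centerCm <- swapped[[3]]@centerCm
  swapped[[3]]@centerCm <- c1
  tsSwap <- generateSession(setup$geometry, swapped, setup$social,
                            sessionSpec(setup$roster, 600, seed = 45))
  resSwap <- crossSessionDecode(train, list(tsSwap), c("m1", "m3"),
                                nShuffles = 0, seed = 6)
  expect_lt(meanAccuracy(resSwap), 0.5)

  # empty test list is allowed
  resEmpty <- crossSessionDecode(train, list(), c("m1", "m3"),
                                 nShuffles = 0, seed = 6)
  expect_length(accuracies(resEmpty), 0L)
})

test_that("cross-context decoding uses triplets containing the pair", {
  train <- sessionFor(42)
  trip <- generateSession(setup$geometry, setup$footprints[c(1, 2, 4)],
                          setup$social,
                          sessionSpec(c("m1", "m2", "m4"), 600, seed = 46),
                          sessionId = "trip46")
  res <- crossContextDecode(train, list(trip), c("m1", "m4"),
                            nShuffles = 0, seed = 8)
  expect_identical(res@protocol, "cross_context")
  expect_length(accuracies(res), 1L)
  expect_gt(meanAccuracy(res), 0.8)
  # a pair broken by the removal leaves no usable test sessions
  resNone <- crossContextDecode(train, list(trip), c("m1", "m3"),
                                nShuffles = 0, seed = 8)
  expect_length(accuracies(resNone), 0L)
  # skipped-with-warning path of the underlying decoder
  expect_warning(crossSessionDecode(train, list(trip), c("m1", "m3"),
                                    nShuffles = 0, seed = 8), "skipped")
})
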