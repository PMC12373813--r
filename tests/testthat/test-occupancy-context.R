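test_that("occupancy maps normalize correctly for simple layouts", {
  # all samples in one cell
  ts <- constantTrajectory(list(a = c(10, 10, 10)), n = 100)
  m <- occupancyMap(ts, "a")
  expect_identical(dim(occupancyGrid(m)), c(16L, 29L))
  expect_equal(sum(occupancyGrid(m)), 1)
  expect_equal(max(occupancyGrid(m)), 1)

  # half the samples in each of two cells
  pos <- matrix(rep(c(10, 10, 10), each = 100), 100, 3)
  pos[51:100, 1] <- 260
  ts2 <- makeTrajectory(list(a = pos))
  g <- occupancyGrid(occupancyMap(ts2, "a"))
  expect_equal(sort(g[g > 0]), c(0.5, 0.5))

  # normalization under missing data
  pos[c(3, 9), ] <- NA
  ts3 <- makeTrajectory(list(a = pos))
  expect_equal(sum(occupancyGrid(occupancyMap(ts3, "a"))), 1)

  # all-missing input is an explicit error
  pos[] <- NA
  expect_error(occupancyMap(makeTrajectory(list(a = pos)), "a"),
               "all samples missing")
})

test_that("uniform occupancy is flat up to binomial noise", {
  set.seed(21)
  n <- 1e5
  pos <- cbind(runif(n, 0, 270), runif(n, 0, 150), runif(n, 0, 200))
  g <- occupancyGrid(occupancyMap(makeTrajectory(list(a = pos)), "a"))
  p <- 1 / 464
  bound <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(max(abs(g - p)), bound)
})

test_that("context-change index D matches its elementwise definition", {
  # identical maps
  m <- randomMap()
  expect_identical(contextChange(m, m), 0)

  # all mass moved one cell over: two cells differ by 1 -> D = 2/464
  g1 <- matrix(0, 16, 29); g1[1, 1] <- 1
  g2 <- matrix(0, 16, 29); g2[1, 2] <- 1
  a <- m; a@grid <- g1
  b <- m; b@grid <- g2
  expect_equal(contextChange(a, b), 2 / 464, tolerance = 1e-12)

  # brute-force oracle on random map pairs, symmetry included
  set.seed(31)
  for (i in 1:25) {
    x <- randomMap(); y <- randomMap()
    acc <- 0
    for (r in 1:16) for (c in 1:29)
      acc <- acc + abs(x@grid[r, c] - y@grid[r, c])
    expect_equal(contextChange(x, y), acc / 464, tolerance = 1e-12)
    expect_identical(contextChange(x, y), contextChange(y, x))
  }

  # shape and identity guards
  small <- new("OccupancyMap", individualId = "m1", sessionId = "s",
               grid = matrix(1), xEdges = c(0, 270), yEdges = c(0, 150))
  expect_error(contextChange(m, small), "shapes")
  other <- randomMap(individual = "zz")
  expect_error(contextChange(m, other), "same individual")
})

test_that("context-change table enumerates the session-pair design", {
  study <- smallStudy()           # 3 quadruple + 1 triplet (m3 removed)
  tab <- contextChangeTable(study)
  for (ind in c("m1", "m2", "m4")) {
    expect_identical(sum(tab$individual == ind &
                           tab$condition == "4in-vs-4in"), 3L)  # C(3,2)
    expect_identical(sum(tab$individual == ind &
                           tab$condition == "4in-vs-triplet:m3"), 3L)
  }
  # the removed individual has no triplet condition rows
  expect_identical(sum(tab$individual == "m3" &
                         tab$condition != "4in-vs-4in"), 0L)
  expect_true(all(tab$D >= 0))
  expect_error(contextChangeTable(study[4]), "two quadruple")
})

test_that("resampled context test is reproducible, powered, and guarded", {
  set.seed(5)
  base <- rnorm(171, 0.02, 0.005)
  r1 <- permutationContextTest(base, base + 0.05, seed = 9)
  expect_lt(r1@meanP, 0.001)
  r2 <- permutationContextTest(base, base + 0.05, seed = 9)
  expect_identical(r1@tValues, r2@tValues)
  expect_length(r1@tValues, 200L)
  expect_error(permutationContextTest(numeric(0), base), "non-empty")
})

test_that("median positions recover elevation structure across sessions", {
  geom <- cageGeometry()
  fps <- list(
    footprintSpec("a", c(60, 40, 60), 15, wallAffinity = 0),
    footprintSpec("b", c(200, 40, 60), 15, wallAffinity = 0),
    footprintSpec("c", c(60, 110, 60), 15, wallAffinity = 0),
    footprintSpec("d", c(200, 110, 130), 15, wallAffinity = 0))  # high z
  ros <- c("a", "b", "c", "d")
  soc <- socialSpec(ros, 0)
  sessions <- lapply(1:19, function(i)
    generateSession(geom, fps, soc,
                    sessionSpec(ros, 20, missingRate = 0, seed = 600 + i),
                    sessionId = sprintf("s%02d", i)))
  mp <- medianPositions(sessions)
  zed <- mp$medians
  bySess <- split(zed, zed$session_id)
  topEverySession <- vapply(bySess, function(df)
    df$individual[which.max(df$z_cm)] == "d", logical(1))
  expect_true(all(topEverySession))
  fz <- mp$friedman[mp$friedman$axis == "z_cm", ]
  expect_lt(fz$p_value, 0.01)
  expect_identical(nrow(mp$pairwise), 3L * 6L)

  # constant trajectories give exact medians
  ct <- constantTrajectory(list(a = c(10, 20, 30), b = c(40, 50, 60)),
                           n = 10, sessionId = "c1")
  ct2 <- constantTrajectory(list(a = c(10, 20, 30), b = c(40, 50, 60)),
                            n = 10, sessionId = "c2")
  cm <- medianPositions(list(ct, ct2))$medians
  expect_identical(cm$x_cm[cm$individual == "a"], c(10, 10))
  expect_identical(cm$z_cm[cm$individual == "b"], c(60, 60))

  # absent individual excludes the session with a warning
  expect_warning(medianPositions(c(sessions[1:3], list(ct))),
                 "excluded")
})
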