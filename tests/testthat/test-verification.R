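# A smooth 2D test field and helpers shared across the blocks.
smoothField <- function(ax, ay, amp = 2)
  outer(ax, ay, function(x, y) amp * exp(-(x^2 + y^2) / 800))

test_that("dose difference follows the global-normalization definition", {
  pts <- cbind(x = c(0, 10), y = 0, z = 0)
  meas <- doseCloud(pts, c(2.0, 1.0))
  calc <- doseCloud(pts, c(1.98, 1.01))
  r <- meanDoseDifference(meas, calc, thresholdPct = 10)
  expect_equal(r$dd, c(-1.0, 0.5))
  expect_equal(r$dd_mean, -0.25)

  # identical distributions
  r0 <- meanDoseDifference(meas, meas)
  expect_equal(r0$dd_mean, 0)
  expect_equal(r0$dd_sd, 0)

  # uniform scaling: DD_i = -meas_i / d_max %
  scaled <- doseCloud(pts, 0.99 * c(2.0, 1.0))
  rs <- meanDoseDifference(meas, scaled, thresholdPct = 0)
  expect_equal(rs$dd, -100 * 0.01 * c(2.0, 1.0) / 2.0)

  # threshold excludes low-dose points; all below -> error
  low <- doseCloud(pts, c(2.0, 0.1))
  expect_equal(length(meanDoseDifference(low, low)$dd), 1)
  expect_error(meanDoseDifference(meas, calc, thresholdPct = 200),
               "threshold")
})

test_that("dd_mean is antisymmetric under swapping up to the normalization change", {
  pts <- cbind(x = seq(-10, 10, 5), y = 0, z = 0)
  a <- doseCloud(pts, c(1, 2, 2.5, 2, 1))
  b <- doseCloud(pts, c(1.1, 1.9, 2.6, 2.2, 0.9))
  r1 <- meanDoseDifference(a, b, thresholdPct = 0)
  r2 <- meanDoseDifference(b, a, thresholdPct = 0)
  expect_equal(r1$dd_mean * maxDose(a), -r2$dd_mean * maxDose(b))
})

test_that("gamma is zero for identical inputs and 1.5 for a flat 3% offset", {
  ax <- seq(-20, 20, 1)
  M <- smoothField(ax, ax)
  grid <- doseGrid(ax, ax, as.numeric(M))
  pts <- as.matrix(expand.grid(x = seq(-10, 10, 2), y = seq(-10, 10, 2),
                               z = 0))
  meas <- doseCloud(pts, evalDose(grid, pts))
  r <- verifyDose(meas, grid)
  expect_equal(r@ddMean, 0)
  expect_true(all(r@gamma == 0))
  expect_equal(r@passRate, 100)

  flatMeas <- doseCloud(pts, rep(1, nrow(pts)))
  flatCalc <- doseGrid(ax, ax, rep(1.03, length(M)))
  g <- gammaGlobal(flatMeas, flatCalc)
  expect_equal(unique(g@gamma), 1.5)
  expect_equal(g@passRate, 0)
})

test_that("the pruned lattice search equals the exhaustive brute force", {
  # 3D grid (below 31^3) with structure in all three axes
  ax <- seq(-14, 14, 2); ay <- seq(-14, 14, 2); az <- seq(-6, 6, 2)
  arr <- array(0, c(length(ax), length(ay), length(az)))
  for (k in seq_along(az))
    arr[, , k] <- smoothField(ax, ay) * (1 - 0.05 * az[k])
  calc <- doseGrid(ax, ay, as.numeric(arr), z = az)

  set.seed(4)
  pts <- cbind(x = runif(25, -6, 6), y = runif(25, -6, 6), z = 0)
  meas <- doseCloud(pts, evalDose(calc, pts) * (1 + runif(25, -0.04, 0.04)))

  opt <- gammaGlobal(meas, calc, thresholdPct = 10)
  brute <- bruteForceGamma(meas, calc, thresholdPct = 10)
  expect_equal(length(opt@gamma), length(brute))
  expect_lt(max(abs(opt@gamma - brute)), 1e-6)
})

test_that("gamma is monotone in the criteria and under lattice refinement", {
  ax <- seq(-25, 25, 1)
  calc <- doseGrid(ax, ax, as.numeric(smoothField(ax, ax)))
  pts <- as.matrix(expand.grid(x = seq(-8, 8, 4), y = seq(-8, 8, 4),
                               z = 0))
  meas <- doseCloud(pts, evalDose(calc, pts) * 1.025)

  g22 <- gammaGlobal(meas, calc, dosePct = 2, dtaMm = 2)
  g32 <- gammaGlobal(meas, calc, dosePct = 3, dtaMm = 2)
  g23 <- gammaGlobal(meas, calc, dosePct = 2, dtaMm = 3)
  expect_true(all(g32@gamma <= g22@gamma + 1e-12))
  expect_true(all(g23@gamma <= g22@gamma + 1e-12))

  coarse <- gammaGlobal(meas, calc, interpStep = 0.5)
  fine <- gammaGlobal(meas, calc, interpStep = 0.1)
  expect_true(all(fine@gamma <= coarse@gamma + 1e-3))
})

test_that("gamma is invariant under relabeling the grid axes", {
  ax <- seq(-20, 20, 1)
  M <- smoothField(ax, ax) + outer(ax, ax, function(x, y) 0.001 * x)
  calc <- doseGrid(ax, ax, as.numeric(M))
  calcT <- doseGrid(ax, ax, as.numeric(t(M)))
  pts <- cbind(x = c(-5, 0, 3), y = c(2, 4, -6), z = 0)
  meas <- doseCloud(pts, evalDose(calc, pts) * 1.02)
  measT <- doseCloud(pts[, c(2, 1, 3)], doseValues(meas))
  g1 <- gammaGlobal(meas, calc)
  g2 <- gammaGlobal(measT, calcT)
  expect_equal(g1@gamma, g2@gamma, tolerance = 1e-12)
})

test_that("points whose search sphere leaves the grid are excluded with a warning", {
  ax <- seq(-10, 10, 1)
  calc <- doseGrid(ax, ax, as.numeric(smoothField(ax, ax)))
  pts <- cbind(x = c(0, 9), y = 0, z = 0)   # the second sphere leaves the grid
  meas <- doseCloud(pts, evalDose(calc, pts))
  expect_warning(g <- gammaGlobal(meas, calc, thresholdPct = 0),
                 "not covered")
  expect_equal(g@nEvaluated, 1L)
  expect_equal(g@nExcluded, 1L)
})

test_that("pooled histograms are order-invariant partitions of the points", {
  a <- c(-1.2, 0.3, 0.8, 2.6)
  b <- c(0.1, -0.4, 1.4)
  h1 <- pooledHistogram(list(a, b), 0.5)
  h2 <- pooledHistogram(list(b, a), 0.5)
  expect_equal(h1, h2)
  expect_equal(sum(h1$count), length(a) + length(b))
  expect_equal(pooledHistogram(list(a), 0.5)$count,
               pooledHistogram(a, 0.5)$count)
  # every bin edge is a multiple of the width
  expect_true(all(abs(h1$lower / 0.5 - round(h1$lower / 0.5)) < 1e-9))
})

test_that("dose CSV round trip preserves clouds", {
  pts <- cbind(x = c(0, 5, -5), y = c(1, 2, 3), z = 0)
  d <- doseCloud(pts, c(1, 2, 0.5))
  f <- tempfile(fileext = ".csv")
  writeDoseCsv(d, f)
  back <- readDoseCsv(f)
  expect_equal(doseValues(back), doseValues(d))
  expect_equal(unname(dosePoints(back)), unname(pts))
})
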