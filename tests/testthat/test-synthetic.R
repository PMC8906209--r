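test_that("the trailing DLG interpolates between mono-block and single-layer values", {
  m <- TipModel()   # single 0.42/0.32, mono -0.47, saturation 5 mm
  expect_equal(trailingDlg(0, m, "proximal"), -0.47)
  expect_equal(trailingDlg(5, m, "proximal"), 0.42)
  expect_equal(trailingDlg(20, m, "proximal"), 0.42)
  expect_equal(trailingDlg(2.5, m, "proximal"), -0.025)
  expect_equal(trailingDlg(c(0, 5, 2.5), m, "distal"),
               c(-0.47, 0.32, -0.075))
  expect_error(trailingDlg(-1, m), ">= 0")

  mShape <- TipModel(shape = function(t, single, mono, tSat)
    ifelse(t >= tSat, single, mono))
  expect_equal(trailingDlg(c(1, 7), mShape, "proximal"),
               c(-0.47, 0.42))
})

test_that("plan generation is deterministic and class-calibrated", {
  p1 <- generateVmatPlan("small", nArcs = 2, nCpPerArc = 15, seed = 77)
  p2 <- generateVmatPlan("small", nArcs = 2, nCpPerArc = 15, seed = 77)
  expect_identical(writePlan(p1), writePlan(p2))
  expect_length(validatePlan(p1), 0)
  p3 <- generateVmatPlan("small", nArcs = 2, nCpPerArc = 15, seed = 78)
  expect_false(identical(writePlan(p1), writePlan(p3)))

  # thousands of (control point, strip) samples: median near the small
  # target's clinical value, within the +/-20% calibration band
  big <- generateVmatPlan("small", nArcs = 3, nCpPerArc = 40, seed = 101)
  st <- planGapTrailingStats(big)
  expect_gte(st@gapQuantiles[["median"]], 14)
  expect_lte(st@gapQuantiles[["median"]], 21)
  expect_gt(st@nGaps, 1000)

  bigL <- generateVmatPlan("large", nArcs = 3, nCpPerArc = 40, seed = 102)
  stL <- planGapTrailingStats(bigL)
  expect_gte(stL@gapQuantiles[["median"]], 33.5 * 0.8)
  expect_lte(stL@gapQuantiles[["median"]], 33.5 * 1.2)
})

test_that("detector layout matches its closed-form count and symmetries", {
  pts <- delta4DetectorPoints(5, 10, centralHalf = 30, half = 100)
  # per axis: 13 central (5 mm) + 2 * 7 outer (10 mm) = 27 coordinates
  nAx <- 13 + 2 * 7
  expect_equal(nrow(pts), nAx^2 + nAx * (nAx - 1))
  plane <- attr(pts, "plane")
  expect_true(all(pts[plane == 1, 3] == 0))
  expect_true(all(pts[plane == 2, 2] == 0))
  expect_false(any(duplicated(pts)))
  # symmetric under 180 degree rotation about the beam axis
  key <- function(p) paste(p[, 1], p[, 2], p[, 3])
  rot <- cbind(-pts[, 1], -pts[, 2], pts[, 3])
  expect_setequal(key(rot), key(pts))

  uni <- delta4DetectorPoints(2, 2, half = 10)
  expect_equal(nrow(uni), 11^2 + 11 * 10)
})

test_that("the dose engine is linear in MU and monotone in the calculated DLG", {
  plan <- staticPlan(prox = list(`15` = c(-15, 15)),
                     dist = list(`14` = c(-15, 15), `15` = c(-15, 15)))
  m <- TipModel(penumbraSigma = 2)
  d1 <- computeDose(plan, m, NULL, "tps", dlgCalc = 0.1)
  plan2 <- plan
  plan2@beams[[1]]@mu <- 2 * plan2@beams[[1]]@mu
  d2 <- computeDose(plan2, m, NULL, "tps", dlgCalc = 0.1)
  expect_equal(doseValues(d2), 2 * doseValues(d1), tolerance = 1e-12)

  prev <- doseValues(d1)
  for (dlg in c(0.5, 0.9, 1.3)) {
    cur <- doseValues(computeDose(plan, m, NULL, "tps", dlgCalc = dlg))
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("a fully open field gives identical measured and tps doses away from the tips", {
  plan <- openFieldPlan()
  m <- TipModel()
  pts <- delta4DetectorPoints(10, 10, half = 80)
  meas <- computeDose(plan, m, pts, "measured")
  tps <- computeDose(plan, m, pts, "tps", dlgCalc = 0.1)
  expect_equal(doseValues(meas), doseValues(tps), tolerance = 1e-12)
})

test_that("the fluence integral scales as gap + DLG (closed form before blur)", {
  plan <- staticPlan(prox = list(`15` = c(-10, 10)),
                     dist = list(`14` = c(-10, 10), `15` = c(-10, 10)))
  m <- bareModel()
  i9 <- sum(doseValues(computeDose(plan, m, NULL, "tps", dlgCalc = 0.9)))
  i1 <- sum(doseValues(computeDose(plan, m, NULL, "tps", dlgCalc = 0.1)))
  expect_equal(i9 / i1, (20 + 0.9) / (20 + 0.1), tolerance = 1e-9)
})

test_that("measured and tps modes agree exactly when trailing is disabled", {
  m <- bareModel(dlgSingle = c(proximal = 0.42, distal = 0.42),
                 dlgMono = 0.42, penumbraSigma = 3)
  plan <- generateVmatPlan("small", nArcs = 1, nCpPerArc = 8, seed = 55)
  meas <- computeDose(plan, m, NULL, "measured")
  tps <- computeDose(plan, m, NULL, "tps", dlgCalc = 0.42)
  expect_equal(doseValues(meas), doseValues(tps), tolerance = 1e-12)
})

test_that("measured-mode noise is seeded and reproducible", {
  plan <- staticPlan(prox = list(`15` = c(-15, 15)),
                     dist = list(`14` = c(-15, 15)))
  m <- TipModel()
  pts <- delta4DetectorPoints(10, 10, half = 40)
  a <- computeDose(plan, m, pts, "measured", noiseSdPct = 0.5, seed = 9)
  b <- computeDose(plan, m, pts, "measured", noiseSdPct = 0.5, seed = 9)
  c2 <- computeDose(plan, m, pts, "measured", noiseSdPct = 0.5, seed = 10)
  expect_identical(doseValues(a), doseValues(b))
  expect_false(identical(doseValues(a), doseValues(c2)))
  expect_true(all(doseValues(a) >= 0))
})

test_that("sweep readings with zero transmission equal (g + DLG_eff)/L", {
  m <- bareModel()
  rd <- simulateSweepReading(seq(2, 20, 2), t = 3, m, "proximal")
  expect_equal(rd$D_g, (rd$g + trailingDlg(3, m, "proximal")) / 120)
  rdS <- simulateSweepReading(10, t = NULL, m, "distal")
  expect_equal(rdS$D_g, (10 + 0.32) / 120)
})
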