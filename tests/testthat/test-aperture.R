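specs <- halcyonLayerSpecs()
strips <- buildStrips(specs$proximal, specs$distal)

test_that("the half-pitch stagger tiles into 58 strips of 5 mm, 56 dual-covered", {
  expect_equal(nrow(strips), 58)
  expect_equal(unique(strips$y_high - strips$y_low), 5)
  expect_equal(sum(!is.na(strips$dist_pair)), 56)
  expect_true(all(is.na(strips$dist_pair[c(1, 58)])))
  expect_equal(range(strips$y_low), c(-145, 140))
  # strips tile without overlap
  expect_equal(strips$y_low[-1], strips$y_high[-58])
})

test_that("strips are mirror-symmetric about the axis", {
  for (k in 1:29) {
    expect_equal(strips$y_low[k], -strips$y_high[59 - k])
    expect_equal(strips$prox_pair[k], 30 - strips$prox_pair[59 - k])
    if (!is.na(strips$dist_pair[k]))
      expect_equal(strips$dist_pair[k], 29 - strips$dist_pair[59 - k])
  }
})

test_that("a non-half-pitch stagger is rejected", {
  badDist <- MlcLayerSpec("distal", 28L, lateralOffset = 3)
  expect_error(buildStrips(specs$proximal, badDist), "half a leaf width")
})

test_that("strip apertures follow the hand geometry", {
  plan <- staticPlan(prox = list(`15` = c(-10, 10)),
                     dist = list(`14` = c(-10, 10)))
  ap <- stripApertures(controlPoints(beams(plan)[[1]])[[1]], strips)
  s <- ap[ap$strip == 29, ]   # strip of prox pair 15 + dist pair 14
  expect_equal(s$gap, 20)
  expect_equal(s$tA, 0)
  expect_equal(s$defA, "tie")

  plan2 <- staticPlan(prox = list(`15` = c(-10, 10)),
                      dist = list(`14` = c(-15, 12)))
  ap2 <- stripApertures(controlPoints(beams(plan2)[[1]])[[1]], strips)
  s2 <- ap2[ap2$strip == 29, ]
  expect_equal(s2$gap, 20)
  expect_equal(c(s2$tA, s2$tB), c(5, 2))
  expect_equal(c(s2$defA, s2$defB), c("proximal", "proximal"))

  plan3 <- staticPlan(prox = list(`15` = c(-10, -2)),
                      dist = list(`14` = c(3, 12)))
  ap3 <- stripApertures(controlPoints(beams(plan3)[[1]])[[1]], strips)
  expect_equal(ap3$gap[ap3$strip == 29], 0)
})

test_that("effective gap never exceeds either single-layer gap", {
  plan <- generateVmatPlan("large", nArcs = 1, nCpPerArc = 10, seed = 21)
  for (cp in controlPoints(beams(plan)[[1]])) {
    ap <- stripApertures(cp, strips)
    pp <- round(leafPositions(cp, "proximal"), 2)  # same 0.01 mm rounding
    pd <- round(leafPositions(cp, "distal"), 2)    # as stripApertures
    gp <- pp[strips$prox_pair, 2] - pp[strips$prox_pair, 1]
    dual <- ap$dual
    gd <- pd[strips$dist_pair[dual], 2] - pd[strips$dist_pair[dual], 1]
    expect_true(all(ap$gap <= gp + 1e-6))
    expect_true(all(ap$gap[dual] <= gd + 1e-6))
  }
})

test_that("trailing classes partition the open edges (sum 100)", {
  plan <- staticPlan(prox = list(`15` = c(-10, 10)),
                     dist = list(`14` = c(-10, 10)))
  st <- planGapTrailingStats(plan)
  expect_equal(unname(st@trailingPct[["overlap"]]), 100)
  expect_equal(sum(st@trailingPct), 100, tolerance = 1e-9)

  for (seed in c(2, 13)) {
    p <- generateVmatPlan("small", nArcs = 2, nCpPerArc = 12, seed = seed)
    for (w in c("unweighted", "mu_weighted")) {
      st <- planGapTrailingStats(p, weighting = w)
      expect_equal(sum(st@trailingPct), 100, tolerance = 1e-3)
    }
  }
})

test_that("handcrafted control point matches an exhaustive hand count", {
  # open strips with known tips:
  # strip 29 = prox 15 (-10,10) + dist 14 (-10,10): tie/tie, gap 20
  # strip 30 = prox 15 + dist 15 (-12,8): gap 18, bank A prox defines
  #   (t=2, lt5), bank B dist defines (t=2, lt5)
  # strip 39 = prox 20 (-30,5) + dist 19 (-25,10): gap 30, bank A dist
  #   defines (t=5, ge5), bank B prox defines (t=5, ge5)
  # strip 40 = prox 20 + dist 20 (closed at 0): gap 0, excluded
  plan <- staticPlan(
    prox = list(`15` = c(-10, 10), `20` = c(-30, 5)),
    dist = list(`14` = c(-10, 10), `15` = c(-12, 8),
                `19` = c(-25, 10)))
  st <- planGapTrailingStats(plan)
  # 6 classified edges total.
  expect_equal(unname(st@trailingPct[["overlap"]]), 100 * 2 / 6)
  expect_equal(unname(st@trailingPct[["proximal_lt5"]]), 100 * 1 / 6)
  expect_equal(unname(st@trailingPct[["distal_lt5"]]), 100 * 1 / 6)
  expect_equal(unname(st@trailingPct[["proximal_ge5"]]), 100 * 1 / 6)
  expect_equal(unname(st@trailingPct[["distal_ge5"]]), 100 * 1 / 6)
  expect_equal(unname(st@gapQuantiles[["median"]]), 20)  # gaps 18, 20, 30
})

test_that("statistics are invariant under control-point reversal (unweighted)", {
  plan <- generateVmatPlan("small", nArcs = 1, nCpPerArc = 10, seed = 31)
  ref <- planGapTrailingStats(plan)
  rev <- plan
  b <- beams(rev)[[1]]
  cps <- rev(controlPoints(b))
  w <- metersetWeights(b)
  for (k in seq_along(cps)) {
    cps[[k]]@index <- k - 1L
    cps[[k]]@weight <- w[k]
  }
  b@controlPoints <- cps
  rev@beams <- list(b)
  st <- planGapTrailingStats(rev)
  expect_equal(st@trailingPct, ref@trailingPct)
  expect_equal(st@gapQuantiles, ref@gapQuantiles)
})

test_that("single-layer conversion puts every edge in the defining t>=5 class", {
  for (def in c("proximal", "distal")) {
    p <- toSingleLayer(
      generateVmatPlan("small", nArcs = 1, nCpPerArc = 10, seed = 17),
      defining = def)
    st <- planGapTrailingStats(p)
    ge5 <- paste0(def, "_ge5")
    expect_equal(unname(st@trailingPct[[ge5]]), 100)
  }
})

test_that("an all-closed plan raises the empty-aperture error", {
  expect_error(planGapTrailingStats(staticPlan()), "empty aperture")
})
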