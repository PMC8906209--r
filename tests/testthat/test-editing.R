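specs <- halcyonLayerSpecs()
strips <- buildStrips(specs$proximal, specs$distal)

test_that("single-layer conversion retracts tracking leaves 5 mm beyond the defining tips", {
  plan <- staticPlan(prox = list(`15` = c(-20, 30)))
  conv <- toSingleLayer(plan, "proximal")
  cp <- controlPoints(beams(conv)[[1]])[[1]]
  # prox pair 15 unchanged
  expect_equal(unname(leafPositions(cp, "proximal")[15, ]), c(-20, 30))
  # both distal pairs overlapping it (14 and 15) track at -25 / +35
  pd <- leafPositions(cp, "distal")
  expect_equal(unname(pd[14, ]), c(-25, 35))
  expect_equal(unname(pd[15, ]), c(-25, 35))
  # a distal pair behind two closed prox pairs tracks the closed tips
  expect_equal(unname(pd[5, ]), c(-5, 5))
})

test_that("retraction must be positive and the conversion is idempotent", {
  plan <- smallTestPlan()
  expect_error(toSingleLayer(plan, "proximal", retraction = 0),
               "retraction")
  once <- toSingleLayer(plan, "distal")
  twice <- toSingleLayer(once, "distal")
  for (ci in seq_along(controlPoints(beams(once)[[1]])))
    for (ly in c("proximal", "distal"))
      expect_equal(
        leafPositions(controlPoints(beams(twice)[[1]])[[ci]], ly),
        leafPositions(controlPoints(beams(once)[[1]])[[ci]], ly))
})

test_that("converted plans keep the defining layer's strip aperture exactly", {
  plan <- generateVmatPlan("small", nArcs = 1, nCpPerArc = 8, seed = 23)
  conv <- toSingleLayer(plan, "proximal")
  for (ci in seq_along(controlPoints(beams(conv)[[1]]))) {
    cp <- controlPoints(beams(conv)[[1]])[[ci]]
    ap <- stripApertures(cp, strips)
    pp <- round(leafPositions(cp, "proximal"), 2)
    defGap <- pmax(0, pp[strips$prox_pair, 2] - pp[strips$prox_pair, 1])
    expect_equal(ap$gap, unname(defGap))
  }
})

test_that("leaf opening widens every pair gap by 2*delta and clamps at travel", {
  plan <- staticPlan(prox = list(`15` = c(-10, 10)),
                     dist = list(`14` = c(-10, 10), `15` = c(-12, 8)))
  expect_identical(applyLeafOpening(plan, 0), plan)

  opened <- applyLeafOpening(plan, 0.4)
  cp <- controlPoints(beams(opened)[[1]])[[1]]
  expect_equal(unname(leafPositions(cp, "proximal")[15, ]),
               c(-10.4, 10.4))
  # effective strip gap grows by exactly 2*delta when both layers open
  apBefore <- stripApertures(controlPoints(beams(plan)[[1]])[[1]], strips)
  apAfter <- stripApertures(cp, strips)
  open <- apBefore$gap > 0
  expect_true(any(open))
  expect_equal(apAfter$gap[open], apBefore$gap[open] + 0.8)

  planEdge <- staticPlan(prox = list(`15` = c(-139.8, 139.9)))
  expect_warning(openedEdge <- applyLeafOpening(planEdge, 0.4),
                 "clamped")
  pe <- leafPositions(controlPoints(beams(openedEdge)[[1]])[[1]],
                      "proximal")
  expect_equal(unname(pe[15, ]), c(-140, 140))
})

test_that("open_only mode leaves closed pairs closed", {
  plan <- staticPlan(prox = list(`15` = c(-10, 10)))
  opened <- applyLeafOpening(plan, 0.4, mode = "open_only")
  p <- leafPositions(controlPoints(beams(opened)[[1]])[[1]], "proximal")
  expect_equal(unname(p[1, ]), c(0, 0))          # closed pair untouched
  expect_equal(unname(p[15, ]), c(-10.4, 10.4))  # open pair widened
})

test_that("opening_for_dlg implements the (target - base)/2 rule on the 0.2 mm grid", {
  expect_equal(openingForDlg(0.9, 0.1), 0.4)
  expect_equal(openingForDlg(0.1, 0.1), 0)
  expect_equal(openingForDlg(1.3, 0.1), 0.6)
  expect_error(openingForDlg(1.0, 0.1), "0.2")   # 0.45 not on 0.1 mm grid
  expect_error(openingForDlg(0.05, 0.1), "baseDlg")
})

test_that("sweep sequences have the stated geometry and constant speed", {
  spec0 <- SweepSpec(gap = 10, trailingLayer = "distal",
                     trailingDistance = 0)
  plan0 <- makeSweepPlan(spec0)
  for (cp in controlPoints(beams(plan0)[[1]])) {
    pp <- leafPositions(cp, "proximal")
    pd <- leafPositions(cp, "distal")
    selP <- pp[, 2] - pp[, 1] > 0
    selD <- pd[, 2] - pd[, 1] > 0
    expect_equal(unique(pp[selP, 1]), unique(pd[selD, 1]))
    expect_equal(unique(pp[selP, 2]), unique(pd[selD, 2]))
  }

  plan20 <- makeSweepPlan(SweepSpec(gap = 10, trailingLayer = "distal",
                                    trailingDistance = 20))
  for (cp in controlPoints(beams(plan20)[[1]])) {
    pd <- leafPositions(cp, "distal")
    sel <- pd[, 2] - pd[, 1] > 0
    expect_equal(unique(pd[sel, 2] - pd[sel, 1]), 50)  # g + 2t
  }

  # equal tip spacing <-> equally spaced cumulative weights
  w <- metersetWeights(beams(plan0)[[1]])
  expect_equal(diff(w), rep(1 / 24, 24), tolerance = 1e-12)
  expect_equal(length(w), 25)  # one CP per 5 mm of the 120 mm sweep

  expect_error(makeSweepPlan(SweepSpec(gap = 20, trailingLayer = "distal",
                                       trailingDistance = 75)),
               "travel")
})

test_that("every sweep of the measurement grids yields a valid plan", {
  for (g in seq(2, 20, by = 2)) {
    p <- makeSweepPlan(SweepSpec(gap = g))
    expect_length(validatePlan(p), 0)
  }
  for (t in c(0, 0.5, 1, 2, 3, 4, 5, 10, 20)) {
    p <- makeSweepPlan(SweepSpec(gap = 10, trailingLayer = "distal",
                                 trailingDistance = t))
    expect_length(validatePlan(p), 0)
  }
})
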