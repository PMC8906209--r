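test_that("DICOM round trip preserves positions to the rounding bound and weights exactly", {
  plan <- generateVmatPlan("small", nArcs = 2, nCpPerArc = 12, seed = 5)
  raw <- writePlan(plan)
  back <- readPlan(raw)
  expect_length(validatePlan(back), 0)
  expect_equal(length(beams(back)), 2)
  for (bi in 1:2) {
    b1 <- beams(plan)[[bi]]
    b2 <- beams(back)[[bi]]
    expect_equal(metersetWeights(b2), metersetWeights(b1))
    expect_equal(beamMU(b2), beamMU(b1))
    for (ci in seq_along(controlPoints(b1))) {
      for (ly in c("proximal", "distal")) {
        p1 <- leafPositions(controlPoints(b1)[[ci]], ly)
        p2 <- leafPositions(controlPoints(b2)[[ci]], ly)
        expect_lt(max(abs(p1 - p2)), 0.05 + 1e-9)
      }
    }
  }
  expect_equal(planMetadata(back)$id, planMetadata(plan)$id)
  expect_equal(planMetadata(back)$target_class, "small")
})

test_that("serialization rounds to 0.1 mm half-up and enforces travel limits", {
  plan <- staticPlan(prox = list(`15` = c(-12.3456, 12.3456)))
  back <- readPlan(writePlan(plan))
  p <- leafPositions(controlPoints(beams(back)[[1]])[[1]], "proximal")
  expect_equal(unname(p[15, ]), c(-12.3, 12.3))

  # half-up ties: +2.65 -> 2.7, -2.65 -> -2.6 (toward +Inf)
  plan2 <- staticPlan(prox = list(`15` = c(-2.65, 2.65)))
  p2 <- leafPositions(
    controlPoints(beams(readPlan(writePlan(plan2)))[[1]])[[1]], "proximal")
  expect_equal(unname(p2[15, ]), c(-2.6, 2.7))

  # at the limit after rounding: accepted
  planEdge <- staticPlan(prox = list(`15` = c(-139.97, 10)))
  pe <- leafPositions(
    controlPoints(beams(readPlan(writePlan(planEdge)))[[1]])[[1]],
    "proximal")
  expect_equal(unname(pe[15, 1]), -140.0)

  # beyond the limit after rounding: rejected
  planBad <- staticPlan(prox = list(`15` = c(-10, 140.06)))
  expect_error(writePlan(planBad), "travel")
})

test_that("reader rejects single-layer and pair-count-mismatched files", {
  plan <- staticPlan(prox = list(`15` = c(-10, 10)))
  # 28 + 28 pairs: geometry error
  specs <- list(proximal = MlcLayerSpec("proximal", 28L),
                distal = MlcLayerSpec("distal", 28L, lateralOffset = 5))
  pp <- cbind(A = rep(0, 28), B = rep(0, 28))
  cps <- lapply(0:1, function(k)
    ControlPoint(k, k, 0, list(proximal = pp, distal = pp)))
  bad <- DualLayerPlan(list(Beam(100, cps, specs)))
  expect_error(readPlan(writePlan(bad)), "geometry error")

  # a file carrying only one MLC device is a single-layer plan
  el <- dualmlc:::.element
  sq <- dualmlc:::.sqElement
  it <- dualmlc:::.item
  sb <- dualmlc:::.strBody
  bld <- it(c(el(0x300A, 0x00B8, "CS", sb("MLCX1")),
              el(0x300A, 0x00BC, "IS", sb("29"))))
  cp <- it(c(el(0x300A, 0x0112, "IS", sb("0")),
             el(0x300A, 0x0134, "DS", sb("0"))))
  beam <- it(c(sq(0x300A, 0x00B6, list(bld)),
               sq(0x300A, 0x0111, list(cp))))
  meta <- c(el(0x0002, 0x0010, "UI",
               sb("1.2.840.10008.1.2.1", as.raw(0))))
  single <- c(raw(128), charToRaw("DICM"),
              el(0x0002, 0x0000, "UL", dualmlc:::.u32le(length(meta))),
              meta, sq(0x300A, 0x00B0, list(beam)))
  expect_error(readPlan(single), "single-layer plan")

  raw <- writePlan(plan)
  expect_s4_class(readPlan(raw), "DualLayerPlan")
})

test_that("validatePlan reports each violated invariant by location", {
  good <- staticPlan(prox = list(`15` = c(-10, 10)))
  expect_length(validatePlan(good), 0)

  crossed <- staticPlan(prox = list(`7` = c(5, -5)))
  issues <- validatePlan(crossed)
  expect_length(issues, 2)  # both control points carry the crossed pair
  expect_match(issues[1], "pair 7")
  expect_match(issues[1], "x_A > x_B")

  pp <- cbind(A = rep(0, 29), B = rep(0, 29))
  pd <- cbind(A = rep(0, 28), B = rep(0, 28))
  cps <- lapply(seq_along(c(0, 0.5, 0.4, 1)), function(k)
    ControlPoint(k - 1L, c(0, 0.5, 0.4, 1)[k], 0,
                 list(proximal = pp, distal = pd)))
  nonmono <- DualLayerPlan(list(Beam(100, cps, halcyonLayerSpecs())))
  issues <- validatePlan(nonmono)
  expect_length(issues, 1)
  expect_match(issues, "decreases at control point 3")
})

test_that("JSON dump round-trips the plan exactly", {
  plan <- generateVmatPlan("large", nArcs = 1, nCpPerArc = 8, seed = 9)
  back <- planFromJSON(planToJSON(plan))
  b1 <- beams(plan)[[1]]
  b2 <- beams(back)[[1]]
  expect_equal(metersetWeights(b2), metersetWeights(b1))
  for (ci in seq_along(controlPoints(b1)))
    for (ly in c("proximal", "distal"))
      expect_equal(leafPositions(controlPoints(b2)[[ci]], ly),
                   leafPositions(controlPoints(b1)[[ci]], ly))
})

test_that("written files are readable by independent DICOM tooling", {
  plan <- staticPlan(prox = list(`15` = c(-20.25, 30.1)),
                     dist = list(`14` = c(-15, 12)))
  f <- tempfile(fileext = ".dcm")
  writePlan(plan, f)
  script <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "assert ds.Modality == 'RTPLAN'",
    "b = ds.BeamSequence[0]",
    "cp = b.ControlPointSequence[0]",
    "pos = {p.RTBeamLimitingDeviceType: list(p.LeafJawPositions)",
    "       for p in cp.BeamLimitingDevicePositionSequence}",
    "print(pos['MLCX1'][14], pos['MLCX1'][14 + 29])",
    "print(pos['MLCX2'][13], pos['MLCX2'][13 + 28])",
    "print(float(cp.CumulativeMetersetWeight))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(f)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0, info = paste(out, collapse = "\n"))
  vals <- as.numeric(unlist(strsplit(out, "[ ]+")))
  expect_equal(vals, c(-20.2, 30.1, -15, 12, 0))
})
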