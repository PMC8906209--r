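#' @import methods
NULL

#' Geometry of one MLC layer
#'
#' Describes one layer of the stacked-and-staggered dual-layer MLC: the
#' proximal (upper) layer carries 29 leaf pairs and the distal (lower) layer
#' 28 pairs, each leaf projecting to 10 mm width at the isocenter plane, so
#' the distal leaf boundaries sit half a leaf width (5 mm) off the proximal
#' ones.  All lengths are mm projected to isocenter; leaf travel is the
#' signed x axis with bank A tips approaching from negative x and bank B
#' from positive x.
#'
#' @slot layerId `"proximal"` or `"distal"`.
#' @slot nPairs number of leaf pairs.
#' @slot leafWidthIso projected leaf width at isocenter (mm).
#' @slot lateralOffset stagger of this layer's leaf boundaries relative to
#'   the proximal layer (mm); 0 for proximal, half a leaf width for distal.
#' @slot travelMin,travelMax leaf travel limits (mm).
#' @slot transmission broad-beam transmission through this layer alone
#'   (fraction).
#' @slot maxSpeed maximum leaf speed (mm/s).
#' @export
setClass("MlcLayerSpec",
  representation(
    layerId       = "character",
    nPairs        = "integer",
    leafWidthIso  = "numeric",
    lateralOffset = "numeric",
    travelMin     = "numeric",
    travelMax     = "numeric",
    transmission  = "numeric",
    maxSpeed      = "numeric"
  )
)

setValidity("MlcLayerSpec", function(object) {
  msg <- character()
  if (!object@layerId %in% c("proximal", "distal"))
    msg <- c(msg, "layerId must be 'proximal' or 'distal'")
  if (length(object@nPairs) != 1L || object@nPairs < 1L)
    msg <- c(msg, "nPairs must be a single count >= 1")
  if (object@leafWidthIso <= 0)
    msg <- c(msg, "leafWidthIso must be > 0")
  if (object@travelMin >= object@travelMax)
    msg <- c(msg, "travelMin must be < travelMax")
  if (object@transmission < 0 || object@transmission >= 1)
    msg <- c(msg, "transmission must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param layerId,nPairs,leafWidthIso,lateralOffset,travelMin,travelMax,transmission,maxSpeed
#'   see the class slots.
#' @rdname MlcLayerSpec-class
#' @export
MlcLayerSpec <- function(layerId, nPairs, leafWidthIso = 10,
                         lateralOffset = 0, travelMin = -140,
                         travelMax = 140, transmission = 0.004,
                         maxSpeed = 50) {
  new("MlcLayerSpec", layerId = layerId, nPairs = as.integer(nPairs),
      leafWidthIso = leafWidthIso, lateralOffset = lateralOffset,
      travelMin = travelMin, travelMax = travelMax,
      transmission = transmission, maxSpeed = maxSpeed)
}

#' Default dual-layer geometry
#'
#' The stock dual-layer MLC geometry: 29 proximal and 28 distal pairs of
#' 10 mm leaves, distal boundaries staggered by 5 mm, leaf travel -140 to
#' +140 mm at up to 50 mm/s.
#'
#' @param transmission named numeric, per-layer broad-beam transmission.
#' @return named list with elements `proximal` and `distal`
#'   ([MlcLayerSpec-class] objects).
#' @export
halcyonLayerSpecs <- function(transmission = c(proximal = 0.004,
                                               distal = 0.004)) {
  list(
    proximal = MlcLayerSpec("proximal", 29L, lateralOffset = 0,
                            transmission = unname(transmission["proximal"])),
    distal   = MlcLayerSpec("distal", 28L, lateralOffset = 5,
                            transmission = unname(transmission["distal"]))
  )
}

#' One VMAT control point
#'
#' Holds the leaf tips of both layers at one control point.  Positions are
#' stored per layer as an `nPairs x 2` matrix with columns `A` and `B`
#' (bank A tip `x_A`, bank B tip `x_B`, mm at isocenter); the pair gap is
#' `x_B - x_A` and closed pairs have `x_A == x_B`.
#'
#' @slot index 0-based control point index.
#' @slot weight cumulative meterset weight in [0, 1].
#' @slot gantry gantry angle (degrees).
#' @slot positions named list (`proximal`, `distal`) of position matrices.
#' @export
setClass("ControlPoint",
  representation(
    index     = "integer",
    weight    = "numeric",
    gantry    = "numeric",
    positions = "list"
  )
)

setValidity("ControlPoint", function(object) {
  msg <- character()
  if (length(object@weight) != 1L || !is.finite(object@weight))
    msg <- c(msg, "weight must be a single finite number")
  for (nm in names(object@positions)) {
    p <- object@positions[[nm]]
    if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p))
      msg <- c(msg, sprintf("positions$%s must be a numeric n x 2 matrix", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @param index,weight,gantry,positions see the class slots.
#' @rdname ControlPoint-class
#' @export
ControlPoint <- function(index, weight, gantry = 0, positions) {
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("A", "B")
    p
  })
  new("ControlPoint", index = as.integer(index), weight = weight,
      gantry = gantry, positions = positions)
}

#' One beam (arc) of a dual-layer plan
#'
#' @slot mu beam meterset (MU).
#' @slot controlPoints list of [ControlPoint-class] objects.
#' @slot layerSpecs named list (`proximal`, `distal`) of
#'   [MlcLayerSpec-class] objects.
#' @export
setClass("Beam",
  representation(
    mu            = "numeric",
    controlPoints = "list",
    layerSpecs    = "list"
  )
)

#' @param mu,controlPoints,layerSpecs see the class slots.
#' @rdname Beam-class
#' @export
Beam <- function(mu, controlPoints, layerSpecs = halcyonLayerSpecs()) {
  new("Beam", mu = mu, controlPoints = controlPoints,
      layerSpecs = layerSpecs)
}

#' A dual-layer MLC treatment plan
#'
#' In-memory model of an RT Plan whose beams carry two MLC layers.  Leaf
#' positions are kept at full precision; the 0.1 mm serialization rounding
#' is applied only by [writePlan()].
#'
#' @slot beams list of [Beam-class] objects.
#' @slot metadata free-form list; `id` and `target_class` round-trip
#'   through the DICOM plan label/name.
#' @export
setClass("DualLayerPlan",
  representation(
    beams    = "list",
    metadata = "list"
  )
)

#' @param beams,metadata see the class slots.
#' @rdname DualLayerPlan-class
#' @export
DualLayerPlan <- function(beams, metadata = list()) {
  new("DualLayerPlan", beams = beams, metadata = metadata)
}

#' Pooled gap-width and leaf-trailing statistics of a plan
#'
#' @slot gapQuantiles named numeric: 25th, 50th and 75th percentile of the
#'   per-strip effective gap over all open (control point, strip) samples.
#' @slot trailingPct named numeric of length 5: percentage of open bank
#'   edges in each trailing class (`proximal_lt5`, `proximal_ge5`,
#'   `distal_lt5`, `distal_ge5`, `overlap`); sums to 100.
#' @slot nGaps,nEdges sample counts behind the percentiles / percentages.
#' @slot weighting `"unweighted"` or `"mu_weighted"`.
#' @export
setClass("GapTrailingStats",
  representation(
    gapQuantiles = "numeric",
    trailingPct  = "numeric",
    nGaps        = "numeric",
    nEdges       = "numeric",
    weighting    = "character"
  )
)

#' Sweeping-gap sequence specification
#'
#' @slot gap sweeping gap width g (mm).
#' @slot sweepDistance sweep length L travelled by the gap center (mm).
#' @slot leafSpeed leaf speed (mm/s), constant between control points.
#' @slot leadingLayer layer forming the gap.
#' @slot trailingLayer character(0) for a single-layer sweep, otherwise the
#'   other layer, trailed at fixed distance behind the leading tips.
#' @slot trailingDistance trailing distance t (mm, >= 0).
#' @slot fieldSize side of the square field containing the sweep (mm).
#' @slot nControlPoints number of control points.
#' @export
setClass("SweepSpec",
  representation(
    gap              = "numeric",
    sweepDistance    = "numeric",
    leafSpeed        = "numeric",
    leadingLayer     = "character",
    trailingLayer    = "character",
    trailingDistance = "numeric",
    fieldSize        = "numeric",
    nControlPoints   = "integer"
  )
)

setValidity("SweepSpec", function(object) {
  msg <- character()
  if (object@gap <= 0) msg <- c(msg, "gap must be > 0")
  if (object@sweepDistance <= 0) msg <- c(msg, "sweepDistance must be > 0")
  if (object@trailingDistance < 0)
    msg <- c(msg, "trailingDistance must be >= 0")
  if (length(object@trailingLayer) &&
      identical(object@trailingLayer, object@leadingLayer))
    msg <- c(msg, "trailingLayer must differ from leadingLayer")
  if (object@nControlPoints < 2L)
    msg <- c(msg, "need at least 2 control points")
  if (length(msg)) msg else TRUE
})

#' @param gap,sweepDistance,leafSpeed,leadingLayer,trailingLayer,trailingDistance,fieldSize,nControlPoints
#'   see the class slots.
#' @rdname SweepSpec-class
#' @export
SweepSpec <- function(gap, sweepDistance = 120, leafSpeed = 5,
                      leadingLayer = "proximal",
                      trailingLayer = character(0),
                      trailingDistance = 0, fieldSize = 100,
                      nControlPoints = as.integer(sweepDistance / 5) + 1L) {
  new("SweepSpec", gap = gap, sweepDistance = sweepDistance,
      leafSpeed = leafSpeed, leadingLayer = leadingLayer,
      trailingLayer = trailingLayer, trailingDistance = trailingDistance,
      fieldSize = fieldSize, nControlPoints = as.integer(nControlPoints))
}

#' Sweeping-gap DLG fit
#'
#' Ordinary least-squares fit of the transmission-corrected dose ratio
#' y = D_g/D_ref against the sweeping gap width g.  The dosimetric leaf gap
#' is minus the x intercept, i.e. `intercept/slope`.
#'
#' @slot slope,intercept OLS coefficients of y on g.
#' @slot dlg dosimetric leaf gap (mm) = intercept/slope.
#' @slot rSquared coefficient of determination.
#' @slot n number of fitted points.
#' @export
setClass("DlgFitResult",
  representation(
    slope     = "numeric",
    intercept = "numeric",
    dlg       = "numeric",
    rSquared  = "numeric",
    n         = "integer"
  )
)

#' Dose distribution on a grid or detector point cloud
#'
#' Either a regular grid (uniformly spaced axes; the dose array is stored
#' with x varying fastest) or an unstructured cloud of detector points.
#' Doses are absolute (Gy).
#'
#' @slot kind `"grid"` or `"cloud"`.
#' @slot axes for grids, named list of axis coordinate vectors `x`, `y`,
#'   `z` (an axis of length 1 means the dose does not vary along it).
#' @slot points for clouds, an `n x 3` matrix of (x, y, z) mm.
#' @slot dose numeric dose vector; for grids in x-fastest order.
#' @slot dMax cached maximum dose.
#' @export
setClass("DoseDistribution",
  representation(
    kind   = "character",
    axes   = "list",
    points = "matrix",
    dose   = "numeric",
    dMax   = "numeric"
  )
)

setValidity("DoseDistribution", function(object) {
  msg <- character()
  if (!object@kind %in% c("grid", "cloud"))
    msg <- c(msg, "kind must be 'grid' or 'cloud'")
  if (any(object@dose < 0)) msg <- c(msg, "dose must be >= 0")
  if (length(object@dose) &&
      abs(object@dMax - max(object@dose)) > 1e-12 * max(1, object@dMax))
    msg <- c(msg, "dMax must equal max(dose)")
  if (object@kind == "grid") {
    n <- prod(vapply(object@axes, length, 1L))
    if (n != length(object@dose))
      msg <- c(msg, "dose length must match grid size")
    for (ax in object@axes) {
      if (length(ax) > 1L) {
        d <- diff(ax)
        if (any(d <= 0) || max(abs(d - d[1])) > 1e-9)
          msg <- c(msg, "grid axes must be uniformly increasing")
      }
    }
  } else {
    if (nrow(object@points) != length(object@dose))
      msg <- c(msg, "points and dose lengths differ")
  }
  if (length(msg)) msg else TRUE
})

#' Measured-vs-calculated verification summary
#'
#' @slot ddMean,ddSd mean and SD of the per-point dose difference, in % of
#'   the maximum measured dose (calculated minus measured; negative means
#'   the calculation underestimates).
#' @slot gammaMean,gammaSd mean and SD of the per-point gamma index.
#' @slot passRate percentage of evaluated points with gamma <= 1.
#' @slot nEvaluated points entering the statistics (measured dose above
#'   threshold and search sphere covered).
#' @slot nExcluded above-threshold points excluded because the calculated
#'   grid did not cover their search sphere.
#' @slot criteria list: dose tolerance (%), DTA (mm), lower dose
#'   threshold (%), normalization.
#' @slot dd,gamma per-point values for the evaluated points.
#' @export
setClass("VerificationResult",
  representation(
    ddMean     = "numeric",
    ddSd       = "numeric",
    gammaMean  = "numeric",
    gammaSd    = "numeric",
    passRate   = "numeric",
    nEvaluated = "integer",
    nExcluded  = "integer",
    criteria   = "list",
    dd         = "numeric",
    gamma      = "numeric"
  )
)

#' Empirical DLG tuning result
#'
#' @slot dlgGrid DLG values (mm) at which the mean dose difference was
#'   evaluated.
#' @slot meanDd pooled mean DD (%) per grid value.
#' @slot slope,intercept OLS line DD = slope * dlg + intercept (%/mm, %).
#' @slot rSquared fit quality of the line.
#' @slot dlgEmp zero crossing of the line (mm).
#' @slot extrapolated TRUE when the zero crossing lies outside the grid.
#' @slot assignedDlg dlgEmp rounded to the assignable base + 0.2k grid (mm).
#' @slot perBankOpening (assignedDlg - base)/2 (mm).
#' @slot base built-in DLG of the dose calculation (mm).
#' @export
setClass("TuningResult",
  representation(
    dlgGrid        = "numeric",
    meanDd         = "numeric",
    slope          = "numeric",
    intercept      = "numeric",
    rSquared       = "numeric",
    dlgEmp         = "numeric",
    extrapolated   = "logical",
    assignedDlg    = "numeric",
    perBankOpening = "numeric",
    base           = "numeric"
  )
)

#' Synthetic leaf-tip transmission model
#'
#' Parameterizes the dose engine's rounded-leaf-tip behaviour: each layer
#' has a single-layer DLG; when the opposite layer trails the defining tip
#' at distance t the effective DLG drops towards the mono-block value
#' `dlgMono` as t goes to 0 and saturates at the single-layer value for
#' t >= `tSat` (piecewise-linear by default, pluggable via `shape`).
#'
#' @slot dlgSingle named numeric (mm): per-layer DLG at saturated trailing.
#' @slot dlgMono DLG (mm) when the two layers' tips coincide (t = 0).
#' @slot tSat trailing distance (mm) beyond which the single-layer DLG
#'   applies.
#' @slot transmission named numeric: per-layer broad-beam transmission.
#' @slot dualTransmission transmission through both layers.
#' @slot penumbraSigma Gaussian penumbra sigma of the engine (mm).
#' @slot muToGy dose per accumulated fluence-weighted MU (Gy/MU).
#' @slot shape optional function `(t, dlgSingle, dlgMono, tSat) -> dlg`
#'   replacing the default piecewise-linear trailing response.
#' @export
setClass("TipModel",
  representation(
    dlgSingle        = "numeric",
    dlgMono          = "numeric",
    tSat             = "numeric",
    transmission     = "numeric",
    dualTransmission = "numeric",
    penumbraSigma    = "numeric",
    muToGy           = "numeric",
    shape            = "ANY"
  )
)

setValidity("TipModel", function(object) {
  msg <- character()
  if (object@tSat <= 0) msg <- c(msg, "tSat must be > 0")
  if (any(object@dlgMono > object@dlgSingle + 1e-12))
    msg <- c(msg, "dlgMono must be <= dlgSingle")
  if (any(object@transmission < 0) || any(object@transmission >= 1) ||
      object@dualTransmission < 0 || object@dualTransmission >= 1)
    msg <- c(msg, "transmissions must be in [0, 1)")
  if (!is.null(object@shape) && !is.function(object@shape))
    msg <- c(msg, "shape must be NULL or a function")
  if (length(msg)) msg else TRUE
})

#' @param dlgSingle,dlgMono,tSat,transmission,dualTransmission,penumbraSigma,muToGy,shape
#'   see the class slots.  Defaults follow typical sweeping-gap
#'   measurements on this MLC type: per-layer DLGs of 0.42/0.32 mm, a
#'   mono-block DLG of -0.47 mm at zero trailing, 5 mm saturation, and a
#'   dual-layer transmission below 1e-4.
#' @rdname TipModel-class
#' @export
TipModel <- function(dlgSingle = c(proximal = 0.42, distal = 0.32),
                     dlgMono = -0.47, tSat = 5,
                     transmission = c(proximal = 0.004, distal = 0.004),
                     dualTransmission = 1e-4, penumbraSigma = 3,
                     muToGy = 0.003, shape = NULL) {
  new("TipModel", dlgSingle = dlgSingle, dlgMono = dlgMono, tSat = tSat,
      transmission = transmission, dualTransmission = dualTransmission,
      penumbraSigma = penumbraSigma, muToGy = muToGy, shape = shape)
}
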