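#' Validate a plan against the dual-layer invariants
#'
#' Checks every beam and control point: both layer specs present, at least
#' two control points, cumulative meterset weights starting at 0, ending at
#' 1 and nondecreasing, `x_A <= x_B` for every pair, and all positions
#' within the travel limits.  This is a reporting operation: it never
#' throws, it returns the list of violations.
#'
#' @param plan a [DualLayerPlan-class].
#' @param ... unused.
#' @return character vector of issues, each naming the beam, control point
#'   and pair concerned; empty when the plan satisfies all invariants.
#' @export
setGeneric("validatePlan", function(plan, ...) standardGeneric("validatePlan"))

#' @rdname accessors
#' @export
setGeneric("beams", function(x) standardGeneric("beams"))

#' @rdname accessors
#' @export
setGeneric("metersetWeights", function(x) standardGeneric("metersetWeights"))

#' @rdname accessors
#' @export
setGeneric("leafPositions", function(x, layer, ...)
  standardGeneric("leafPositions"))

#' @rdname accessors
#' @export
setGeneric("layerSpec", function(x, layer) standardGeneric("layerSpec"))

#' @rdname accessors
#' @export
setGeneric("beamMU", function(x) standardGeneric("beamMU"))

#' @rdname DoseDistribution-class
#' @export
setGeneric("maxDose", function(x) standardGeneric("maxDose"))

#' Evaluate a dose distribution at arbitrary points
#'
#' For grids, multilinear interpolation along the axes the grid varies in
#' (an axis of length 1 is ignored, i.e. the dose is constant along it).
#' For clouds, points must coincide with stored points (matched to 1e-6 mm).
#'
#' @param x a [DoseDistribution-class].
#' @param points `n x 3` matrix of (x, y, z) mm.
#' @return numeric dose vector at `points`.
#' @export
setGeneric("evalDose", function(x, points) standardGeneric("evalDose"))

#' Effective trailing-dependent DLG of the tip model
#'
#' Piecewise-linear interpolation between the mono-block DLG at zero
#' trailing and the layer's single-layer DLG at the saturation distance
#' (or the model's pluggable `shape` function).
#'
#' @param t trailing distance(s), mm, >= 0.
#' @param model a [TipModel-class].
#' @param layer `"proximal"` or `"distal"`: the layer defining the edge.
#' @return effective DLG (mm), vectorized over `t`.
#' @export
setGeneric("trailingDlg", function(t, model, layer = "proximal")
  standardGeneric("trailingDlg"))
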