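#' Accessors for plan objects
#'
#' @param x a [DualLayerPlan-class], [Beam-class] or [ControlPoint-class].
#' @param layer `"proximal"` or `"distal"`.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("beams", "DualLayerPlan", function(x) x@beams)

#' @rdname accessors
#' @export
setMethod("beamMU", "Beam", function(x) x@mu)

#' @rdname accessors
#' @export
setMethod("beamMU", "DualLayerPlan", function(x)
  vapply(x@beams, function(b) b@mu, numeric(1)))

#' @rdname accessors
#' @export
setMethod("metersetWeights", "Beam", function(x)
  vapply(x@controlPoints, function(cp) cp@weight, numeric(1)))

#' @rdname accessors
#' @export
setMethod("layerSpec", "Beam", function(x, layer) x@layerSpecs[[layer]])

#' @rdname accessors
#' @export
setMethod("layerSpec", "DualLayerPlan", function(x, layer)
  x@beams[[1]]@layerSpecs[[layer]])

#' @rdname accessors
#' @export
setMethod("leafPositions", "ControlPoint", function(x, layer, ...)
  x@positions[[layer]])

#' @rdname accessors
#' @export
controlPoints <- function(x) x@controlPoints

#' @rdname accessors
#' @export
planMetadata <- function(x) x@metadata

setMethod("show", "MlcLayerSpec", function(object) {
  cat(sprintf(
    "MlcLayerSpec '%s': %d pairs x %.1f mm (offset %.1f mm), travel [%g, %g] mm, T = %.4f\n",
    object@layerId, object@nPairs, object@leafWidthIso,
    object@lateralOffset, object@travelMin, object@travelMax,
    object@transmission))
})

setMethod("show", "Beam", function(object) {
  cat(sprintf("Beam: %.1f MU, %d control points, layers: %s\n",
              object@mu, length(object@controlPoints),
              paste(names(object@layerSpecs), collapse = " + ")))
})

setMethod("show", "DualLayerPlan", function(object) {
  cat(sprintf("DualLayerPlan '%s' (%s): %d beam(s)\n",
              if (is.null(object@metadata$id)) "?" else object@metadata$id,
              if (is.null(object@metadata$target_class)) "unclassified"
              else object@metadata$target_class,
              length(object@beams)))
  for (b in object@beams) show(b)
})

#' @rdname validatePlan
setMethod("validatePlan", "DualLayerPlan", function(plan, ...) {
  issues <- character()
  say <- function(...) issues <<- c(issues, sprintf(...))
  for (bi in seq_along(plan@beams)) {
    beam <- plan@beams[[bi]]
    if (!all(c("proximal", "distal") %in% names(beam@layerSpecs))) {
      say("beam %d: missing layer spec(s)", bi)
      next
    }
    cps <- beam@controlPoints
    if (length(cps) < 2L) say("beam %d: fewer than 2 control points", bi)
    w <- vapply(cps, function(cp) cp@weight, numeric(1))
    if (length(w)) {
      if (abs(w[1]) > 1e-9)
        say("beam %d: first cumulative weight is %g, not 0", bi, w[1])
      if (abs(w[length(w)] - 1) > 1e-9)
        say("beam %d: last cumulative weight is %g, not 1", bi, w[length(w)])
      bad <- which(diff(w) < -1e-9)
      for (k in bad)
        say("beam %d: cumulative weight decreases at control point %d",
            bi, k + 1L)
    }
    for (ci in seq_along(cps)) {
      cp <- cps[[ci]]
      for (ly in c("proximal", "distal")) {
        spec <- beam@layerSpecs[[ly]]
        p <- cp@positions[[ly]]
        if (is.null(p)) {
          say("beam %d cp %d: missing %s positions", bi, ci, ly)
          next
        }
        if (nrow(p) != spec@nPairs) {
          say("beam %d cp %d: %s has %d pairs, spec says %d",
              bi, ci, ly, nrow(p), spec@nPairs)
          next
        }
        bad <- which(p[, 1] > p[, 2] + 1e-9)
        for (k in bad)
          say("beam %d cp %d: %s pair %d has x_A > x_B (%.3f > %.3f)",
              bi, ci, ly, k, p[k, 1], p[k, 2])
        out <- which(p[, 1] < spec@travelMin - 1e-6 |
                     p[, 2] > spec@travelMax + 1e-6)
        for (k in out)
          say("beam %d cp %d: %s pair %d outside travel limits", bi, ci, ly, k)
      }
    }
  }
  issues
})

# ---- JSON round trip (plain-text plan fixtures) ------------------------

#' Serialize a plan to JSON
#'
#' A plain-text dump of the in-memory plan, convenient for fixtures and
#' diffing.  Unlike [writePlan()] it applies no rounding.
#'
#' @param plan a [DualLayerPlan-class].
#' @param path optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
planToJSON <- function(plan, path = NULL) {
  obj <- list(
    metadata = plan@metadata,
    beams = lapply(plan@beams, function(b) list(
      mu = b@mu,
      layers = lapply(b@layerSpecs, function(s) list(
        layerId = s@layerId, nPairs = s@nPairs,
        leafWidthIso = s@leafWidthIso, lateralOffset = s@lateralOffset,
        travelMin = s@travelMin, travelMax = s@travelMax,
        transmission = s@transmission, maxSpeed = s@maxSpeed)),
      controlPoints = lapply(b@controlPoints, function(cp) list(
        index = cp@index, weight = cp@weight, gantry = cp@gantry,
        positions = lapply(cp@positions, function(p)
          list(A = unname(p[, 1]), B = unname(p[, 2])))))
    ))
  )
  txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a plan from its JSON dump
#'
#' @param source JSON string or path to a file written by [planToJSON()].
#' @return a [DualLayerPlan-class].
#' @export
planFromJSON <- function(source) {
  obj <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  beams <- lapply(obj$beams, function(b) {
    specs <- lapply(b$layers, function(s)
      MlcLayerSpec(s$layerId, s$nPairs, s$leafWidthIso, s$lateralOffset,
                   s$travelMin, s$travelMax, s$transmission, s$maxSpeed))
    cps <- lapply(b$controlPoints, function(cp) {
      pos <- lapply(cp$positions, function(p)
        cbind(A = unlist(p$A), B = unlist(p$B)))
      ControlPoint(cp$index, cp$weight, cp$gantry, pos)
    })
    Beam(b$mu, cps, specs)
  })
  DualLayerPlan(beams, metadata = obj$metadata)
}
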