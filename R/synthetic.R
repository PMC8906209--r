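# Synthetic study material: VMAT-like dual-layer plans, a leaf-tip
# fluence engine with trailing-dependent tip transmission, sweeping-gap
# reading simulation, and a biplanar diode-array point layout.

#' @rdname trailingDlg
setMethod("trailingDlg", "numeric", function(t, model, layer = "proximal") {
  if (any(t < 0)) stop("trailing distance must be >= 0")
  single <- unname(model@dlgSingle[layer])
  if (is.na(single)) stop("unknown layer: ", layer)
  if (is.function(model@shape))
    return(model@shape(t, single, model@dlgMono, model@tSat))
  model@dlgMono + (single - model@dlgMono) * pmin(t, model@tSat) / model@tSat
})

setMethod("show", "TipModel", function(object) {
  cat(sprintf(
    "TipModel: DLG single %.2f/%.2f mm (prox/dist), mono %.2f mm, t_sat %g mm\n",
    object@dlgSingle[["proximal"]], object@dlgSingle[["distal"]],
    object@dlgMono, object@tSat))
  cat(sprintf("  transmission %.4f/%.4f (dual %.1e), penumbra sigma %g mm\n",
              object@transmission[["proximal"]],
              object@transmission[["distal"]],
              object@dualTransmission, object@penumbraSigma))
})

# Run code with a temporary RNG state seeded from `seed`.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a sweeping-gap chamber reading
#'
#' Closed-form emulation of the sweeping-gap measurement under the tip
#' model: the dose ratio is the open dwell fraction plus the tip term,
#' `(g + DLG_eff)/L`, plus the leakage terms that [correctedRatio()]
#' subtracts (single-layer-shielded dwell charged at the leading layer's
#' transmission, dual-shielded at the dual transmission), so correction
#' followed by [fitDlg()] recovers the model DLG exactly.  Optional
#' multiplicative chamber noise (`noiseSd`, relative sd) is applied to the
#' sweeping-field reading; the open-field normalizer is a single
#' high-dose reading and is taken as noiseless.
#'
#' @param g gap width(s), mm.
#' @param t trailing distance (mm) of the other layer, or `NULL` for a
#'   single-layer sweep (other layer retracted).  `t = 0` means trailing
#'   with coincident tips (mono-block edge), not "no trailing".
#' @param model a [TipModel-class].
#' @param layer sweeping (leading) layer.
#' @param sweepDistance sweep length L (mm).
#' @param noiseSd relative sd of the chamber reading (e.g. 0.002).
#' @param seed RNG seed for the noise.
#' @return data.frame with columns `g`, `t`, `trailed`, `layer`, `D_g`,
#'   `D_ref`.
#' @export
simulateSweepReading <- function(g, t = NULL, model = TipModel(),
                                 layer = "proximal", sweepDistance = 120,
                                 noiseSd = 0, seed = NULL) {
  if (any(g <= 0)) stop("g must be > 0")
  L <- sweepDistance
  trailed <- !is.null(t)
  tv <- if (trailed) t else 0
  dlgEff <- if (trailed) trailingDlg(tv, model, layer) else
    unname(model@dlgSingle[layer])
  tLead <- unname(model@transmission[layer])
  leak <- if (trailed)
    tLead * 2 * tv / L + model@dualTransmission * pmax(0, L - g - 2 * tv) / L
  else tLead * (L - g) / L
  dg <- (g + dlgEff) / L + leak
  if (noiseSd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(dg), 0, noiseSd) else
      withSeed(seed, stats::rnorm(length(dg), 0, noiseSd))
    dg <- dg * (1 + noise)
  }
  data.frame(g = g, t = tv, trailed = trailed, layer = layer,
             D_g = dg, D_ref = 1)
}

#' Biplanar diode-array sample points
#'
#' Two orthogonal detector planes through the isocenter with denser
#' sampling in the central region, the typical layout of a biplanar diode
#' array (vendor-typical, configurable; not a calibrated device model).
#' Plane 1 spans x-y at z = 0, plane 2 spans x-z at y = 0 (its z = 0 row
#' is dropped so no point is duplicated).  The point set is symmetric
#' under 180 degree rotation about the beam axis and deterministically
#' ordered.
#'
#' @param spacingCentral spacing inside the central region (mm).
#' @param spacingOuter spacing outside it (mm); set equal to
#'   `spacingCentral` for a uniform grid.
#' @param centralHalf half-size of the central region (mm).
#' @param half half-extent of each plane (mm).
#' @return `n x 3` matrix of (x, y, z) with attribute `plane` (1 or 2).
#' @export
delta4DetectorPoints <- function(spacingCentral = 5, spacingOuter = 10,
                                 centralHalf = 30, half = 100) {
  axis <- if (spacingCentral == spacingOuter) {
    seq(-half, half, by = spacingCentral)
  } else {
    c(seq(-half, -centralHalf - spacingOuter, by = spacingOuter),
      seq(-centralHalf, centralHalf, by = spacingCentral),
      seq(centralHalf + spacingOuter, half, by = spacingOuter))
  }
  p1 <- as.matrix(expand.grid(x = axis, y = axis, z = 0,
                              KEEP.OUT.ATTRS = FALSE))
  zAxis <- axis[axis != 0]
  p2 <- as.matrix(expand.grid(x = axis, y = 0, z = zAxis,
                              KEEP.OUT.ATTRS = FALSE))
  pts <- rbind(p1, p2)
  attr(pts, "plane") <- rep(c(1L, 2L), c(nrow(p1), nrow(p2)))
  pts
}

# ---- VMAT-like plan generator ------------------------------------------

.CLASS_PARAMS <- list(
  # gapAmp calibrated analytically so the pooled per-strip gap median
  # lands near the clinical targets (17.5 mm small, 33.5 mm large)
  small = list(ry = 30, gapAmp = 24, muRange = c(220, 280)),
  large = list(ry = 75, gapAmp = 54, muRange = c(180, 240))
)

#' Generate a synthetic dual-layer VMAT plan
#'
#' Emulates clinical arc sequences for a small (prostate-like) or large
#' (pelvic-like) target: an elliptical aperture envelope with smooth
#' sinusoidal modulation and center wander per control point, and
#' per-pair, per-bank layer offsets drawn from a seeded mixture (point
#' mass at 0, uniform (0,5) mm, uniform [5,20] mm) that produces the full
#' range of trailing classes -- complete overlap, short trailing and
#' saturated trailing on either defining layer.  Deterministic for a
#' fixed seed.
#'
#' @param targetClass `"small"` or `"large"`.
#' @param nArcs number of arcs (beams).
#' @param nCpPerArc control points per arc.
#' @param seed integer seed (required for reproducibility).
#' @return a [DualLayerPlan-class] that passes [validatePlan()].
#' @export
generateVmatPlan <- function(targetClass = c("small", "large"),
                             nArcs = 3, nCpPerArc = 90, seed) {
  targetClass <- match.arg(targetClass)
  if (missing(seed)) stop("seed is required")
  par <- .CLASS_PARAMS[[targetClass]]
  specs <- halcyonLayerSpecs()
  yProx <- (seq_len(specs$proximal@nPairs) - 15) * 10    # pair centers
  yDist <- (seq_len(specs$distal@nPairs) - 14.5) * 10

  drawOffsets <- function(n, pZero) {
    z <- stats::runif(n) < pZero
    mag <- ifelse(stats::runif(n) < 0.5, stats::runif(n, 0, 5),
                  stats::runif(n, 5, 20))
    ifelse(z, 0, mag)
  }

  withSeed(seed, {
    beams <- lapply(seq_len(nArcs), function(arc) {
      psi0 <- stats::runif(1, 0, 2 * pi)
      kap <- stats::runif(1, 0.02, 0.05)
      phC <- stats::runif(2, 0, 2 * pi)
      opA <- drawOffsets(length(yProx), 0.6)
      opB <- drawOffsets(length(yProx), 0.6)
      odA <- drawOffsets(length(yDist), 0.5)
      odB <- drawOffsets(length(yDist), 0.5)
      # each distal pair tracks the envelope of one of the two proximal
      # pairs it overlaps, so zero-offset pairs have coincident tips
      # (complete overlap, t = 0) as clinical sequences do
      distRef <- seq_along(yDist) + (stats::runif(length(yDist)) < 0.5)
      incr <- stats::runif(nCpPerArc - 1, 0.5, 1.5)
      weights <- c(0, cumsum(incr) / sum(incr))
      gDir <- if (arc %% 2 == 1) 1 else -1
      gantry <- gDir * seq(-179.9, 179.9, length.out = nCpPerArc)

      edge <- function(y, phase) {
        # modulation depth grows toward the field periphery: the target
        # center stays near fully open from every angle, as clinical
        # optimizers produce, which keeps the maximum dose stable across
        # sequence edits
        depth <- 0.3 + 0.6 * pmin(1, abs(y) / par$ry)
        m <- 1 - depth * (0.5 + 0.5 * sin(4 * pi * phase + psi0 + kap * y))
        ell2 <- 1 - (y / par$ry)^2
        ghalf <- ifelse(ell2 > 0,
                        par$gapAmp / 2 * sqrt(pmax(ell2, 0)) * m, 0)
        ctr <- 6 * sin(2 * pi * phase + phC[1]) +
          4 * sin(y / 40 + phC[2])
        list(a = ctr - ghalf, b = ctr + ghalf, open = ghalf > 0.4,
             ctr = ctr)
      }
      applyOffsets <- function(e, offA, offB, spec) {
        a <- ifelse(e$open, e$a - offA, e$ctr)
        b <- ifelse(e$open, e$b + offB, e$ctr)
        a <- pmax(a, spec@travelMin)
        b <- pmin(b, spec@travelMax)
        cbind(A = pmin(a, b), B = b)
      }
      cps <- lapply(seq_len(nCpPerArc), function(k) {
        phase <- (k - 1) / (nCpPerArc - 1)
        eP <- edge(yProx, phase)
        eD <- lapply(eP, function(v) v[distRef])
        ControlPoint(k - 1L, weights[k], gantry[k], list(
          proximal = applyOffsets(eP, opA, opB, specs$proximal),
          distal = applyOffsets(eD, odA, odB, specs$distal)))
      })
      Beam(stats::runif(1, par$muRange[1], par$muRange[2]), cps, specs)
    })
    DualLayerPlan(beams, metadata = list(
      id = sprintf("%s-%06d", targetClass, abs(seed) %% 1e6),
      target_class = targetClass, seed = seed,
      uid = sprintf("%s.%d.%d.%d", .UID_ROOT, abs(seed) %% 1e7,
                    nArcs, nCpPerArc)))
  })
}

# ---- leaf-tip dose engine ----------------------------------------------

# Fluence row of one strip over the x grid (fractional pixel coverage so
# sub-resolution DLG edge shifts integrate exactly).
.stripRow <- function(xc, dx, tips, dlgA, dlgB, tProx, tDist, tDual) {
  if (is.null(tips$dist)) {
    a <- tips$prox[1]; b <- tips$prox[2]
    if (b - a <= 0 && dlgA + dlgB <= 0) return(rep(tProx, length(xc)))
    e1 <- a - dlgA / 2; e2 <- b + dlgB / 2
    if (e2 <= e1) return(rep(tProx, length(xc)))
    return(tProx + (1 - tProx) * pixelCoverage(xc, dx, e1, e2))
  }
  ap <- tips$prox[1]; bp <- tips$prox[2]
  ad <- tips$dist[1]; bd <- tips$dist[2]
  A <- max(ap, ad); B <- min(bp, bd)
  if (B > A) {
    tsA <- if (ap >= ad) tProx else tDist    # defining layer blocks alone
    tsB <- if (bp <= bd) tProx else tDist
    e1 <- A - dlgA / 2
    e2 <- B + dlgB / 2
    if (e2 <= e1) e1 <- e2 <- (e1 + e2) / 2
    e0 <- min(min(ap, ad), e1)
    e3 <- max(max(bp, bd), e2)
    row <- rep(tDual, length(xc))
    row <- row + (tsA - tDual) * pixelCoverage(xc, dx, e0, e1)
    row <- row + (1 - tDual) * pixelCoverage(xc, dx, e1, e2)
    row + (tsB - tDual) * pixelCoverage(xc, dx, e2, e3)
  } else {
    # disjoint or closed: each layer's opening is shielded by the other
    row <- rep(tDual, length(xc))
    row <- row + (tDist - tDual) * pixelCoverage(xc, dx, ap, bp)
    row + (tProx - tDual) * pixelCoverage(xc, dx, ad, bd)
  }
}

#' Compute dose with the synthetic leaf-tip engine
#'
#' A 2D fluence-times-Gaussian dose model in the isocenter plane: per
#' control point each 5 mm strip contributes an open interval bounded by
#' the defining tips moved outward by half the effective DLG per bank,
#' the single-shielded margins at the defining layer's transmission and
#' the doubly shielded remainder at the dual transmission; control points
#' are summed with trapezoidal meterset weighting, blurred with a
#' Gaussian penumbra and scaled to Gy.  In `"measured"` mode the
#' effective DLG per bank follows the trailing distance via
#' [trailingDlg()] (single-layer DLG for lone-layer strips); in `"tps"`
#' mode a constant `dlgCalc` is used regardless of trailing, reproducing
#' a planning system that does not model the leaf-trailing effect.  Depth
#' dose, divergence and gantry rotation are deliberately ignored: every
#' quantity of interest is a difference between two engine runs on the
#' same geometry.
#'
#' @param plan a [DualLayerPlan-class].
#' @param model a [TipModel-class].
#' @param points optional `n x 3` detector points; `NULL` returns the
#'   full 2D grid.
#' @param mode `"measured"` or `"tps"`.
#' @param dlgCalc constant DLG of the tps mode (mm).
#' @param noiseSdPct Gaussian noise sd, % of the maximum dose (measured
#'   mode with `points` only).
#' @param seed RNG seed for the noise.
#' @param gridDx grid spacing (mm).
#' @return a [DoseDistribution-class] (grid, or cloud at `points`).
#' @export
computeDose <- function(plan, model = TipModel(), points = NULL,
                        mode = c("measured", "tps"), dlgCalc = 0.1,
                        noiseSdPct = 0, seed = NULL, gridDx = 1) {
  mode <- match.arg(mode)
  ax <- seq(-160, 160, by = gridDx)
  ay <- seq(-150, 150, by = gridDx)
  M <- matrix(0, length(ax), length(ay))
  tProx <- unname(model@transmission["proximal"])
  tDist <- unname(model@transmission["distal"])
  tDual <- model@dualTransmission

  for (beam in plan@beams) {
    strips <- buildStrips(beam@layerSpecs$proximal, beam@layerSpecs$distal)
    # per-strip y coverage weights on the grid columns
    yCov <- lapply(seq_len(nrow(strips)), function(s) {
      w <- pixelCoverage(ay, gridDx, strips$y_low[s], strips$y_high[s])
      cols <- which(w > 0)
      list(cols = cols, w = w[cols])
    })
    dmu <- trapezoidWeights(metersetWeights(beam)) * beam@mu
    for (k in seq_along(beam@controlPoints)) {
      if (dmu[k] <= 0) next
      cp <- beam@controlPoints[[k]]
      pp <- cp@positions$proximal
      pd <- cp@positions$distal
      for (s in seq_len(nrow(strips))) {
        ip <- strips$prox_pair[s]
        id <- strips$dist_pair[s]
        tips <- list(prox = pp[ip, ],
                     dist = if (is.na(id)) NULL else pd[id, ])
        if (is.null(tips$dist)) {
          open <- tips$prox[2] > tips$prox[1]
          dlgA <- dlgB <- if (!open) 0 else if (mode == "tps") dlgCalc
            else unname(model@dlgSingle["proximal"])
        } else {
          A <- max(tips$prox[1], tips$dist[1])
          B <- min(tips$prox[2], tips$dist[2])
          if (B <= A) {
            dlgA <- dlgB <- 0
          } else if (mode == "tps") {
            dlgA <- dlgB <- dlgCalc
          } else {
            tA <- abs(tips$prox[1] - tips$dist[1])
            tB <- abs(tips$prox[2] - tips$dist[2])
            layA <- if (tips$prox[1] >= tips$dist[1]) "proximal" else
              "distal"
            layB <- if (tips$prox[2] <= tips$dist[2]) "proximal" else
              "distal"
            dlgA <- trailingDlg(tA, model, layA)
            dlgB <- trailingDlg(tB, model, layB)
          }
        }
        row <- .stripRow(ax, gridDx, tips, dlgA, dlgB, tProx, tDist,
                         tDual)
        yc <- yCov[[s]]
        M[, yc$cols] <- M[, yc$cols] + (dmu[k] * row) %o% yc$w
      }
    }
  }

  M <- gaussianBlur2d(M, gridDx, gridDx, model@penumbraSigma)
  M <- M * model@muToGy

  if (is.null(points)) {
    return(doseGrid(ax, ay, as.numeric(M)))
  }
  points <- as.matrix(points)
  d <- bilinearGrid(ax, ay, M, points[, 1], points[, 2])
  if (mode == "measured" && noiseSdPct > 0) {
    sdAbs <- noiseSdPct / 100 * max(d)
    noise <- if (is.null(seed)) stats::rnorm(length(d), 0, sdAbs) else
      withSeed(seed, stats::rnorm(length(d), 0, sdAbs))
    d <- pmax(d + noise, 0)
  }
  doseCloud(points, d)
}
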