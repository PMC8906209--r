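# Leaf-sequence editing: single-layer conversion, symmetric leaf opening,
# and sweeping-gap test sequences.

# Map each tracking-layer pair to the defining-layer pairs it overlaps
# (one or two, because of the half-pitch stagger).
.overlapMap <- function(trackSpec, defSpec) {
  tb <- .leafBoundaries(trackSpec)
  db <- .leafBoundaries(defSpec)
  lapply(seq_len(trackSpec@nPairs), function(j) {
    lo <- tb[j]; hi <- tb[j + 1]
    which(pmin(hi, db[-1]) - pmax(lo, db[-length(db)]) > 1e-9)
  })
}

.mapPositions <- function(plan, fn) {
  beamsOut <- lapply(seq_along(plan@beams), function(bi) {
    beam <- plan@beams[[bi]]
    cps <- lapply(seq_along(beam@controlPoints), function(ci) {
      cp <- beam@controlPoints[[ci]]
      cp@positions <- fn(cp@positions, beam, bi, ci)
      cp
    })
    beam@controlPoints <- cps
    beam
  })
  plan@beams <- beamsOut
  plan
}

#' Convert a dual-layer plan to a single-layer leaf sequence
#'
#' Keeps one layer's leaf sequence unchanged (the defining layer) and
#' retracts the other layer's leaves `retraction` mm beyond the defining
#' tips, the same idea as jaw tracking: over the (up to two) defining
#' pairs a staggered tracking leaf overlaps, its bank A tip goes to the
#' minimum defining bank A tip minus the retraction and its bank B tip to
#' the maximum defining bank B tip plus the retraction, clamped to the
#' travel limits.  This removes leaf trailing (every open edge ends up in
#' the t >= retraction class) without changing the effective aperture
#' wherever clamping does not bind.  Tracking leaves behind closed
#' defining pairs track the closed tips the same way.
#'
#' @param plan a [DualLayerPlan-class].
#' @param defining `"proximal"` or `"distal"`.
#' @param retraction tracking distance (mm), must be > 0; default 5.
#' @return the converted [DualLayerPlan-class].
#' @export
toSingleLayer <- function(plan, defining = c("proximal", "distal"),
                          retraction = 5) {
  defining <- match.arg(defining)
  if (!is.numeric(retraction) || retraction <= 0)
    stop("retraction must be > 0")
  tracking <- setdiff(c("proximal", "distal"), defining)
  maps <- NULL
  plan <- .mapPositions(plan, function(pos, beam, bi, ci) {
    if (is.null(pos[[defining]]))
      stop("defining layer '", defining, "' missing in beam ", bi)
    if (is.null(maps))
      maps <<- .overlapMap(beam@layerSpecs[[tracking]],
                           beam@layerSpecs[[defining]])
    spec <- beam@layerSpecs[[tracking]]
    def <- pos[[defining]]
    trk <- vapply(maps, function(ov) {
      if (!length(ov)) return(c(spec@travelMin, spec@travelMax))
      c(min(def[ov, 1]) - retraction, max(def[ov, 2]) + retraction)
    }, numeric(2))
    pos[[tracking]] <- cbind(A = pmax(trk[1, ], spec@travelMin),
                             B = pmin(trk[2, ], spec@travelMax))
    pos
  })
  plan@metadata$sequence <- paste0(defining, "_single")
  plan
}

#' Open leaf pairs symmetrically
#'
#' Moves every affected bank A tip out by `delta` and bank B tip by
#' `+delta` (pair gap grows by `2 * delta`), clamped to the travel limits;
#' meterset weights and MU are untouched.  This is how an effective DLG
#' change is realized on a machine whose built-in DLG cannot be edited:
#' opening each bank by `(DLG_target - DLG_built_in)/2` makes the dose
#' calculation behave as if the DLG were `DLG_target`.
#'
#' @param plan a [DualLayerPlan-class].
#' @param delta per-bank opening (mm), >= 0.
#' @param layers layers to open (default both).
#' @param mode `"all_pairs"` opens every pair (including closed ones);
#'   `"open_only"` skips pairs with gap <= 0.1 mm, avoiding the leakage
#'   slits that opening closed pairs would create.
#' @return the edited [DualLayerPlan-class]; a warning reports how many
#'   tips were clamped at the travel limits.
#' @export
applyLeafOpening <- function(plan, delta,
                             layers = c("proximal", "distal"),
                             mode = c("all_pairs", "open_only")) {
  mode <- match.arg(mode)
  if (!is.numeric(delta) || delta < 0) stop("delta must be >= 0")
  if (delta == 0) return(plan)
  nClamped <- 0L
  plan <- .mapPositions(plan, function(pos, beam, bi, ci) {
    for (ly in layers) {
      spec <- beam@layerSpecs[[ly]]
      p <- pos[[ly]]
      sel <- if (mode == "open_only") p[, 2] - p[, 1] > 0.1 else
        rep(TRUE, nrow(p))
      a <- p[sel, 1] - delta
      b <- p[sel, 2] + delta
      nClamped <<- nClamped + sum(a < spec@travelMin) +
        sum(b > spec@travelMax)
      p[sel, 1] <- pmax(a, spec@travelMin)
      p[sel, 2] <- pmin(b, spec@travelMax)
      pos[[ly]] <- p
    }
    pos
  })
  if (nClamped > 0L)
    warning(nClamped, " leaf tip(s) clamped at the travel limits")
  plan
}

#' Per-bank opening realizing a target effective DLG
#'
#' The built-in DLG of the dose calculation cannot be edited, so a target
#' DLG is emulated by opening each bank by
#' `(target_dlg - base_dlg) / 2`.  Because stored leaf positions are
#' rounded to 0.1 mm, the opening must itself be a multiple of 0.1 mm,
#' i.e. the target DLG must sit on the `base + 0.2k` assignment grid.
#'
#' @param targetDlg desired effective DLG (mm), >= `baseDlg`.
#' @param baseDlg built-in DLG of the dose calculation (mm); default 0.1.
#' @return per-bank opening (mm).
#' @export
openingForDlg <- function(targetDlg, baseDlg = 0.1) {
  if (targetDlg < baseDlg - 1e-9)
    stop("targetDlg must be >= baseDlg")
  delta <- (targetDlg - baseDlg) / 2
  if (abs(delta * 10 - round(delta * 10)) > 1e-6)
    stop(sprintf(paste0(
      "target DLG %.3f mm is not assignable: the 0.1 mm position ",
      "resolution restricts assignments to the %.1f + 0.2k mm grid"),
      targetDlg, baseDlg))
  round(delta * 10) / 10
}

#' Build a sweeping-gap test sequence
#'
#' The leading layer forms a constant gap of width g whose center travels
#' the sweep distance L at constant leaf speed (cumulative meterset weight
#' linear in tip displacement), symmetric about the beam axis.  Only the
#' leading-layer pairs lying fully inside the square field participate;
#' the rest are closed at park.  With a trailing layer, its same-bank tips
#' sit exactly t outside the leading tips (trailing pair gap g + 2t);
#' without one, the other layer is fully retracted.
#'
#' @param spec a [SweepSpec-class].
#' @return a [DualLayerPlan-class] with one static beam.
#' @export
makeSweepPlan <- function(spec) {
  validObject(spec)
  specs <- halcyonLayerSpecs()
  lead <- spec@leadingLayer
  trail <- if (length(spec@trailingLayer)) spec@trailingLayer else NULL
  g <- spec@gap
  L <- spec@sweepDistance
  t <- spec@trailingDistance
  lim <- specs[[lead]]
  if (L / 2 + g / 2 + t > lim@travelMax)
    stop("gap + trailing exceed the travel limits over the sweep")

  nCp <- spec@nControlPoints
  centers <- seq(-L / 2, L / 2, length.out = nCp)
  weights <- (centers + L / 2) / L

  inField <- function(s) {
    b <- .leafBoundaries(s)
    which(b[-length(b)] >= -spec@fieldSize / 2 - 1e-9 &
          b[-1] <= spec@fieldSize / 2 + 1e-9)
  }
  park <- function(s) {
    p <- matrix(s@travelMin, s@nPairs, 2)
    colnames(p) <- c("A", "B")
    p
  }
  open <- function(s) {
    p <- cbind(A = rep(s@travelMin, s@nPairs),
               B = rep(s@travelMax, s@nPairs))
    p
  }

  other <- setdiff(c("proximal", "distal"), lead)
  cps <- lapply(seq_len(nCp), function(k) {
    c0 <- centers[k]
    posLead <- park(specs[[lead]])
    sel <- inField(specs[[lead]])
    posLead[sel, 1] <- c0 - g / 2
    posLead[sel, 2] <- c0 + g / 2
    posOther <- if (is.null(trail)) open(specs[[other]]) else {
      p <- park(specs[[other]])
      selT <- inField(specs[[other]])
      p[selT, 1] <- c0 - g / 2 - t
      p[selT, 2] <- c0 + g / 2 + t
      p
    }
    pos <- list()
    pos[[lead]] <- posLead
    pos[[other]] <- posOther
    ControlPoint(k - 1L, weights[k], 0, pos[c("proximal", "distal")])
  })

  mu <- L / spec@leafSpeed  # seconds of delivery; nominal 1 MU/s
  DualLayerPlan(list(Beam(mu, cps, specs)),
                metadata = list(
                  id = sprintf("sweep_g%g_t%g_%s", g, t, lead),
                  sweep = list(gap = g, trailing = t, leading = lead,
                               trailingLayer = trail, L = L)))
}
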