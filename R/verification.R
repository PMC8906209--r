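# Measured-vs-calculated dose comparison: global dose difference, global
# gamma index, pooled histograms.

#' Construct a regular-grid dose distribution
#'
#' @param x,y,z axis coordinate vectors (mm), each uniformly spaced; an
#'   axis of length 1 means the dose does not vary along it.
#' @param dose numeric array/vector of doses (Gy), x varying fastest.
#' @return a [DoseDistribution-class] of kind `"grid"`.
#' @export
doseGrid <- function(x, y, dose, z = 0) {
  new("DoseDistribution", kind = "grid",
      axes = list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
      points = matrix(numeric(0), 0, 3), dose = as.numeric(dose),
      dMax = max(dose))
}

#' Construct a detector point-cloud dose distribution
#'
#' @param points `n x 3` matrix of (x, y, z) mm.
#' @param dose dose per point (Gy).
#' @return a [DoseDistribution-class] of kind `"cloud"`.
#' @export
doseCloud <- function(points, dose) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y", "z")
  new("DoseDistribution", kind = "cloud", axes = list(),
      points = points, dose = as.numeric(dose), dMax = max(dose))
}

#' @rdname DoseDistribution-class
#' @param x a [DoseDistribution-class].
#' @export
setMethod("maxDose", "DoseDistribution", function(x) x@dMax)

#' @rdname DoseDistribution-class
#' @export
doseValues <- function(x) x@dose

#' @rdname DoseDistribution-class
#' @export
dosePoints <- function(x) {
  if (x@kind == "cloud") return(x@points)
  g <- expand.grid(x = x@axes$x, y = x@axes$y, z = x@axes$z,
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

setMethod("show", "DoseDistribution", function(object) {
  if (object@kind == "grid") {
    dims <- vapply(object@axes, length, 1L)
    cat(sprintf("DoseDistribution (grid %s): max %.4g Gy\n",
                paste(dims, collapse = " x "), object@dMax))
  } else {
    cat(sprintf("DoseDistribution (cloud, %d points): max %.4g Gy\n",
                nrow(object@points), object@dMax))
  }
})

setMethod("evalDose", "DoseDistribution", function(x, points) {
  points <- as.matrix(points)
  if (x@kind == "cloud") {
    key <- function(p) paste(round(p[, 1], 6), round(p[, 2], 6),
                             round(p[, 3], 6))
    idx <- match(key(points), key(x@points))
    if (anyNA(idx))
      stop("cloud distributions can only be evaluated at their own points")
    return(x@dose[idx])
  }
  ax <- x@axes$x; ay <- x@axes$y; az <- x@axes$z
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  if (nz == 1L) {
    M <- matrix(x@dose, nx, ny)
    return(bilinearGrid(ax, ay, M, points[, 1], points[, 2]))
  }
  # trilinear: interpolate the two bracketing z slices
  fz <- (points[, 3] - az[1]) / (az[2] - az[1])
  if (any(fz < -1e-9 | fz > nz - 1 + 1e-9))
    stop("interpolation point outside grid")
  fz <- pmin(pmax(fz, 0), nz - 1)
  k0 <- pmin(floor(fz), nz - 2)
  tz <- fz - k0
  arr <- array(x@dose, c(nx, ny, nz))
  out <- numeric(nrow(points))
  for (k in sort(unique(k0))) {
    sel <- k0 == k
    lo <- bilinearGrid(ax, ay, arr[, , k + 1], points[sel, 1],
                       points[sel, 2])
    hi <- bilinearGrid(ax, ay, arr[, , k + 2], points[sel, 1],
                       points[sel, 2])
    out[sel] <- (1 - tz[sel]) * lo + tz[sel] * hi
  }
  out
})

#' Read/write dose distributions as plain CSV
#'
#' Columns `x`, `y`, `z`, `dose`.  [readDoseCsv()] returns a cloud; use
#' the grid constructor directly for regular grids.
#'
#' @param path CSV file.
#' @export
readDoseCsv <- function(path) {
  df <- utils::read.csv(path)
  doseCloud(as.matrix(df[, c("x", "y", "z")]), df$dose)
}

#' @rdname readDoseCsv
#' @param x a [DoseDistribution-class].
#' @export
writeDoseCsv <- function(x, path) {
  df <- as.data.frame(dosePoints(x))
  df$dose <- doseValues(x)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Global dose difference between measured and calculated distributions
#'
#' Per point, `DD_i = 100 * (D_calc_i - D_meas_i) / max(D_meas)` (global
#' normalization): a negative mean says the calculation underestimates the
#' measurement.  Statistics are taken over the reference (measured) points
#' whose measured dose reaches the threshold; the calculated distribution
#' is evaluated at the measured points (grid interpolation or identical
#' cloud).
#'
#' @param measured reference [DoseDistribution-class] (detector cloud or
#'   grid).
#' @param calculated [DoseDistribution-class] evaluable at the measured
#'   points.
#' @param thresholdPct lower dose threshold, % of the maximum measured
#'   dose; points below it are excluded (set 0 to keep all).
#' @return list with `dd_mean`, `dd_sd`, `dd` (per evaluated point, %),
#'   and `index` (which measured points entered).
#' @export
meanDoseDifference <- function(measured, calculated, thresholdPct = 10) {
  pts <- dosePoints(measured)
  meas <- doseValues(measured)
  dmax <- maxDose(measured)
  calc <- evalDose(calculated, pts)
  sel <- meas >= thresholdPct / 100 * dmax
  if (!any(sel))
    stop("no measured point above the ", thresholdPct, "% threshold")
  dd <- 100 * (calc[sel] - meas[sel]) / dmax
  list(dd_mean = mean(dd), dd_sd = stats::sd(dd), dd = dd,
       index = which(sel))
}

# Offset lattice within the search sphere, sorted by distance; only axes
# the evaluated grid varies in are searched.
.gammaOffsets <- function(active, step, radius) {
  k <- seq(-floor(radius / step + 1e-9), floor(radius / step + 1e-9)) * step
  ax <- lapply(active, function(a) if (a) k else 0)
  off <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  r2 <- rowSums(off^2)
  keep <- r2 <= radius^2 + 1e-9
  off <- off[keep, , drop = FALSE]
  r2 <- r2[keep]
  o <- order(r2)
  list(offsets = off[o, , drop = FALSE], r2 = r2[o])
}

#' Global gamma index of measured vs calculated distributions
#'
#' For every reference (measured) point above the dose threshold the gamma
#' index is the minimum over evaluated positions r within
#' `searchRadiusFactor * dta` of
#' `sqrt(|r - r_i|^2 / dta^2 + (D_eval(r) - D_meas_i)^2 / tol^2)`, where
#' `tol` is `dosePct`% of the maximum measured dose (global normalization;
#' `"local"` uses the point's own measured dose).  The evaluated
#' distribution is interpolated multilinearly on a lattice of spacing
#' `interpStep` covering the search sphere; the search (in compiled code)
#' scans lattice offsets in order of increasing distance and stops once
#' the distance term alone exceeds the best gamma, which is exact on the
#' lattice.  Reference points whose search sphere is not fully covered by
#' the evaluated grid are excluded with a warning.
#'
#' @param measured reference [DoseDistribution-class].
#' @param calculated evaluated [DoseDistribution-class]; must be a grid.
#' @param dosePct dose-difference criterion (% of max measured dose).
#' @param dtaMm distance-to-agreement criterion (mm).
#' @param thresholdPct lower dose threshold (% of max measured dose).
#' @param searchRadiusFactor search sphere radius in units of `dtaMm`.
#' @param interpStep interpolation lattice step (mm).
#' @param normalization `"global"` or `"local"` dose normalization.
#' @return a [VerificationResult-class] (gamma statistics and pass rate;
#'   `dd` slots are filled by [verifyDose()]).
#' @export
gammaGlobal <- function(measured, calculated, dosePct = 2, dtaMm = 2,
                        thresholdPct = 10, searchRadiusFactor = 3,
                        interpStep = 0.2,
                        normalization = c("global", "local")) {
  normalization <- match.arg(normalization)
  if (calculated@kind != "grid")
    stop("the evaluated (calculated) distribution must be a grid")
  pts <- dosePoints(measured)
  meas <- doseValues(measured)
  dmax <- maxDose(measured)
  sel <- meas >= thresholdPct / 100 * dmax
  if (!any(sel)) stop("no measured point above the threshold")
  pts <- pts[sel, , drop = FALSE]
  meas <- meas[sel]

  ax <- calculated@axes
  active <- vapply(ax, function(a) length(a) > 1L, logical(1))
  R <- searchRadiusFactor * dtaMm
  lat <- .gammaOffsets(active, interpStep, R)

  # coverage of the search sphere, per active axis
  covered <- rep(TRUE, nrow(pts))
  for (d in 1:3) {
    a <- ax[[d]]
    if (length(a) > 1L) {
      covered <- covered & pts[, d] - R >= a[1] - 1e-9 &
        pts[, d] + R <= a[length(a)] + 1e-9
    }
  }
  doseTol <- if (normalization == "global")
    rep(dosePct / 100 * dmax, length(meas))
  else dosePct / 100 * meas

  gam <- gammaSearchCpp(pts, meas, ax$x, ax$y, ax$z, calculated@dose,
                        lat$offsets, lat$r2 / dtaMm^2, doseTol, covered,
                        TRUE)
  nExcl <- sum(!covered)
  if (nExcl > 0L)
    warning(nExcl, " reference point(s) excluded: search sphere not ",
            "covered by the evaluated grid")
  gv <- gam[covered]
  new("VerificationResult",
      ddMean = NA_real_, ddSd = NA_real_,
      gammaMean = mean(gv), gammaSd = stats::sd(gv),
      passRate = 100 * mean(gv <= 1),
      nEvaluated = length(gv), nExcluded = as.integer(nExcl),
      criteria = list(dose_pct = dosePct, dta_mm = dtaMm,
                      threshold_pct = thresholdPct,
                      normalization = normalization,
                      search_radius_factor = searchRadiusFactor,
                      interp_step = interpStep),
      dd = numeric(0), gamma = gv)
}

#' Full verification: dose difference plus gamma
#'
#' Convenience wrapper running [meanDoseDifference()] and [gammaGlobal()]
#' with a shared threshold and assembling a complete
#' [VerificationResult-class].
#'
#' @inheritParams gammaGlobal
#' @inheritParams meanDoseDifference
#' @export
verifyDose <- function(measured, calculated, dosePct = 2, dtaMm = 2,
                       thresholdPct = 10, searchRadiusFactor = 3,
                       interpStep = 0.2,
                       normalization = c("global", "local")) {
  dd <- meanDoseDifference(measured, calculated, thresholdPct)
  res <- gammaGlobal(measured, calculated, dosePct, dtaMm, thresholdPct,
                     searchRadiusFactor, interpStep, normalization)
  res@ddMean <- dd$dd_mean
  res@ddSd <- dd$dd_sd
  res@dd <- dd$dd
  res
}

setMethod("show", "VerificationResult", function(object) {
  cr <- object@criteria
  cat(sprintf("VerificationResult (%g%%/%g mm, threshold %g%%, %s):\n",
              cr$dose_pct, cr$dta_mm, cr$threshold_pct,
              cr$normalization))
  if (!is.na(object@ddMean))
    cat(sprintf("  DD:    mean %+.2f%%, SD %.2f%%\n",
                object@ddMean, object@ddSd))
  cat(sprintf("  gamma: mean %.3f, SD %.3f, pass rate %.2f%% (n = %d",
              object@gammaMean, object@gammaSd, object@passRate,
              object@nEvaluated))
  if (object@nExcluded > 0L)
    cat(sprintf(", %d excluded", object@nExcluded))
  cat(")\n")
})

#' Pooled histogram of per-point values
#'
#' Pools per-point dose differences or gamma values over any number of
#' verifications (sum of verifications, not plan by plan) and bins them
#' with deterministic edges: multiples of `binWidth` spanning the pooled
#' range, so pooling is invariant to the order of the inputs.
#'
#' @param results list of numeric vectors (or a single vector).
#' @param binWidth bin width, in the units of the values.
#' @return data.frame with `lower`, `upper`, `mid`, `count`.
#' @export
pooledHistogram <- function(results, binWidth) {
  v <- unlist(results, use.names = FALSE)
  if (!length(v)) stop("nothing to pool")
  if (binWidth <= 0) stop("binWidth must be > 0")
  lo <- floor(min(v) / binWidth) * binWidth
  hi <- ceiling(max(v) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  edges <- seq(lo, hi + binWidth / 2, by = binWidth)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             mid = edges[-length(edges)] + binWidth / 2, count = counts)
}
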