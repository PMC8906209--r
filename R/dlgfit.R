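# Sweeping-gap analysis: transmission correction, least-squares DLG
# extraction, and the DLG-vs-trailing-distance curve.

#' Transmission-corrected sweeping-gap dose ratio
#'
#' During a sweep of length L the chamber sees the open gap for a dwell
#' fraction g/L and is otherwise shielded.  In a single-layer sweep (no
#' trailing layer) the blocked dwell fraction (L - g)/L is shielded by the
#' sweeping layer alone and is charged at that layer's transmission.  With
#' a trailing layer at distance t, a dwell fraction 2t/L is shielded by
#' the leading layer only (the chamber is inside the trailing layer's
#' wider gap) and the remaining (L - g - 2t)/L by both layers, charged at
#' the dual transmission.  Subtracting these leakage terms from D_g/D_ref
#' leaves the tip contribution (g + DLG)/L, linear in g.
#'
#' @param readings data.frame with columns `g` (gap width, mm), `t`
#'   (trailing distance, mm), `trailed` (logical: trailing layer
#'   present), `D_g`, `D_ref` (chamber readings).
#' @param tLayer transmission of the layer shielding the single-covered
#'   region (the sweeping/leading layer).
#' @param tDual transmission through both layers; defaults to 0 as the
#'   dual-layer leakage is below 1e-4.
#' @param sweepDistance sweep length L (mm).
#' @return corrected ratio y, one value per reading.
#' @export
correctedRatio <- function(readings, tLayer, tDual = 0,
                           sweepDistance = 120) {
  L <- sweepDistance
  stopifnot(tDual >= 0, tLayer >= tDual, tLayer < 1)
  g <- readings$g
  t <- if (is.null(readings$t)) rep(0, length(g)) else readings$t
  trailed <- if (is.null(readings$trailed)) t > 0 else readings$trailed
  if (any(readings$D_ref <= 0)) stop("D_ref must be > 0")
  if (any(g <= 0 | g > L)) stop("need 0 < g <= L")
  ratio <- readings$D_g / readings$D_ref
  leak <- ifelse(trailed,
                 tLayer * 2 * t / L + tDual * pmax(0, L - g - 2 * t) / L,
                 tLayer * (L - g) / L)
  ratio - leak
}

#' Fit the DLG from corrected sweep readings
#'
#' Ordinary least squares of the corrected ratio y on the gap width g.
#' The tip contribution makes y = (g + DLG)/L, so the DLG is minus the x
#' intercept of the line, `intercept/slope`.  The fit is exact on
#' collinear input.
#'
#' @param g gap widths (mm), at least two distinct values.
#' @param y corrected ratios (same length).
#' @return a [DlgFitResult-class].
#' @export
fitDlg <- function(g, y) {
  if (is.data.frame(g)) { y <- g$y; g <- g$g }
  if (length(unique(g)) < 2L) stop("need >= 2 distinct gap widths")
  fit <- stats::lm.fit(cbind(1, g), y)
  b0 <- fit$coefficients[1]
  b1 <- fit$coefficients[2]
  if (!is.finite(b1) || b1 <= 0)
    stop("non-physical fit: slope must be > 0")
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else 1
  new("DlgFitResult", slope = unname(b1), intercept = unname(b0),
      dlg = unname(b0 / b1), rSquared = min(max(r2, 0), 1),
      n = length(g))
}

setMethod("show", "DlgFitResult", function(object) {
  cat(sprintf(
    "DlgFitResult: DLG = %.3f mm (slope %.3e /mm, intercept %.3e, R^2 = %.6f, n = %d)\n",
    object@dlg, object@slope, object@intercept, object@rSquared, object@n))
})

#' DLG as a function of trailing distance
#'
#' Collects per-trailing-distance fits into a sorted curve and flags
#' segments where the DLG decreases with increasing t (physically the
#' curve rises from the mono-block value to the single-layer plateau).
#'
#' @param fits named list of [DlgFitResult-class]; names are the trailing
#'   distances in mm.
#' @param tol monotonicity tolerance (mm).
#' @return data.frame sorted by `t` with columns `t`, `dlg`, `r_squared`,
#'   `nonmonotonic` (TRUE where dlg dropped below the previous t by more
#'   than `tol`).
#' @export
trailingCurve <- function(fits, tol = 1e-6) {
  if (length(fits) < 2L) stop("need fits at >= 2 trailing distances")
  t <- as.numeric(names(fits))
  if (anyNA(t)) stop("fits must be named by trailing distance")
  o <- order(t)
  dlg <- vapply(fits, function(f) f@dlg, numeric(1))[o]
  r2 <- vapply(fits, function(f) f@rSquared, numeric(1))[o]
  data.frame(t = t[o], dlg = dlg, r_squared = r2,
             nonmonotonic = c(FALSE, diff(dlg) < -tol))
}

#' Read sweeping-gap readings from CSV
#'
#' Expects columns `g`, `t`, `D_g`, `D_ref` and optionally `trailed` and
#' `layer`; `trailed` defaults to `t > 0`.
#'
#' @param path CSV file.
#' @return data.frame of readings suitable for [correctedRatio()].
#' @export
readSweepReadings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("g", "t", "D_g", "D_ref")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)),
                                    collapse = ", "))
  if (is.null(df$trailed)) df$trailed <- df$t > 0
  df
}
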