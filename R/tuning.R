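# Empirical DLG tuning: mean DD over a DLG grid, zero crossing, and
# rounding to the assignable grid.

#' Mean dose difference over a grid of effective DLG values
#'
#' For each DLG value the plans are re-edited with the per-bank opening
#' that realizes it ([openingForDlg()], [applyLeafOpening()]), the dose is
#' recalculated by the supplied engine with unchanged MU, and the mean DD
#' against the fixed measurements is pooled (unweighted mean of per-plan
#' means).  Engine failures on individual plans are reported and the
#' remaining plans carry on.
#'
#' @param plans list of [DualLayerPlan-class] (typically single-layer
#'   sequences of one layer).
#' @param measurements list of measured [DoseDistribution-class], parallel
#'   to `plans`.
#' @param dlgValues DLG grid (mm); each must be assignable from `base`.
#' @param doseEngine function(plan) -> calculated
#'   [DoseDistribution-class] evaluable at the measurement points.
#' @param base built-in DLG of the engine (mm).
#' @param thresholdPct lower dose threshold for the DD statistics.
#' @param layers which layer(s) to open; default both.
#' @param mode opening mode passed to [applyLeafOpening()]:
#'   `"all_pairs"` (the literal editing rule, which also opens closed
#'   pairs into thin slits) or `"open_only"`.
#' @return data.frame with columns `dlg` and `mean_dd`; the per-plan
#'   matrix is attached as attribute `"per_plan"`.
#' @export
evaluateDlgGrid <- function(plans, measurements, dlgValues, doseEngine,
                            base = 0.1, thresholdPct = 10,
                            layers = c("proximal", "distal"),
                            mode = c("all_pairs", "open_only")) {
  mode <- match.arg(mode)
  stopifnot(length(plans) == length(measurements))
  perPlan <- matrix(NA_real_, length(dlgValues), length(plans),
                    dimnames = list(format(dlgValues), NULL))
  for (di in seq_along(dlgValues)) {
    delta <- openingForDlg(dlgValues[di], base)
    for (pi in seq_along(plans)) {
      res <- tryCatch({
        p <- if (delta > 0)
          applyLeafOpening(plans[[pi]], delta, layers = layers,
                           mode = mode)
        else plans[[pi]]
        calc <- doseEngine(p)
        meanDoseDifference(measurements[[pi]], calc,
                           thresholdPct)$dd_mean
      }, error = function(e) {
        warning("plan ", pi, " at DLG ", dlgValues[di], " mm failed: ",
                conditionMessage(e))
        NA_real_
      })
      perPlan[di, pi] <- res
    }
  }
  out <- data.frame(dlg = dlgValues,
                    mean_dd = rowMeans(perPlan, na.rm = TRUE))
  attr(out, "per_plan") <- perPlan
  out
}

#' Zero crossing of mean DD versus DLG
#'
#' The mean DD changes linearly with the DLG, so the empirically adjusted
#' DLG is found by an OLS line through all grid points and its zero
#' crossing, interpolating or extrapolating as needed (extrapolation is
#' flagged).
#'
#' @param grid data.frame with columns `dlg` and `mean_dd` (>= 2 rows),
#'   e.g. from [evaluateDlgGrid()].
#' @param slopeTol minimum |slope| (%/mm) below which the DD is declared
#'   insensitive to the DLG.
#' @return list with `dlg_emp`, `slope`, `intercept`, `r_squared`,
#'   `extrapolated`.
#' @export
findDlgEmp <- function(grid, slopeTol = 1e-6) {
  if (nrow(grid) < 2L) stop("need >= 2 grid points")
  fit <- stats::lm.fit(cbind(1, grid$dlg), grid$mean_dd)
  b0 <- unname(fit$coefficients[1])
  b1 <- unname(fit$coefficients[2])
  if (!is.finite(b1) || abs(b1) < slopeTol)
    stop("DD insensitive to DLG: |slope| below tolerance")
  ssTot <- sum((grid$mean_dd - mean(grid$mean_dd))^2)
  r2 <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else 1
  dlgEmp <- -b0 / b1
  list(dlg_emp = dlgEmp, slope = b1, intercept = b0,
       r_squared = min(max(r2, 0), 1),
       extrapolated = dlgEmp < min(grid$dlg) - 1e-9 ||
         dlgEmp > max(grid$dlg) + 1e-9)
}

#' Round an empirical DLG to the assignable grid
#'
#' Stored leaf positions are rounded to 0.1 mm, so per-bank openings come
#' in 0.1 mm steps and assignable DLG values in 0.2 mm steps above the
#' built-in base: `base + 0.2k`, `k >= 0`.  The empirical DLG is rounded
#' to the nearest assignable value, ties up.
#'
#' @param dlgEmp empirical DLG (mm).
#' @param base built-in DLG (mm).
#' @param step assignment grid step (mm).
#' @return list with `assigned_dlg` and `per_bank_opening`
#'   (`(assigned - base)/2`).
#' @export
assignDlg <- function(dlgEmp, base = 0.1, step = 0.2) {
  if (step <= 0) stop("step must be > 0")
  k <- max(0, floor((dlgEmp - base) / step + 0.5 + 1e-9))
  assigned <- round((base + k * step) * 1e6) / 1e6
  list(assigned_dlg = assigned,
       per_bank_opening = round((assigned - base) / 2 * 1e6) / 1e6)
}

# Assemble a TuningResult from the grid evaluation + zero crossing.
.tuningResult <- function(grid, emp, asg, base) {
  new("TuningResult", dlgGrid = grid$dlg, meanDd = grid$mean_dd,
      slope = emp$slope, intercept = emp$intercept,
      rSquared = emp$r_squared, dlgEmp = emp$dlg_emp,
      extrapolated = emp$extrapolated, assignedDlg = asg$assigned_dlg,
      perBankOpening = asg$per_bank_opening, base = base)
}

#' Tune the DLG from plans and measurements in one call
#'
#' Runs [evaluateDlgGrid()], [findDlgEmp()] and [assignDlg()].
#'
#' @inheritParams evaluateDlgGrid
#' @param step assignment grid step (mm).
#' @return a [TuningResult-class].
#' @export
tuneDlg <- function(plans, measurements, dlgValues, doseEngine,
                    base = 0.1, step = 0.2, thresholdPct = 10,
                    layers = c("proximal", "distal"),
                    mode = c("all_pairs", "open_only")) {
  grid <- evaluateDlgGrid(plans, measurements, dlgValues, doseEngine,
                          base, thresholdPct, layers, mode)
  emp <- findDlgEmp(grid)
  asg <- assignDlg(emp$dlg_emp, base, step)
  res <- .tuningResult(grid, emp, asg, base)
  attr(res, "per_plan") <- attr(grid, "per_plan")
  res
}

setMethod("show", "TuningResult", function(object) {
  cat("TuningResult:\n")
  cat("  grid (mm):   ", paste(format(object@dlgGrid), collapse = "  "),
      "\n")
  cat("  mean DD (%): ",
      paste(sprintf("%+.3f", object@meanDd), collapse = "  "), "\n")
  cat(sprintf("  slope %.3f %%/mm (R^2 = %.4f)\n",
              object@slope, object@rSquared))
  cat(sprintf("  DLG_emp = %.3f mm%s -> assigned %.1f mm (opening %.1f mm/bank)\n",
              object@dlgEmp,
              if (object@extrapolated) " (extrapolated)" else "",
              object@assignedDlg, object@perBankOpening))
})
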