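# Strip decomposition of the staggered dual layer and Table-1-style
# gap/trailing statistics.

#' Decompose the stagger into 5 mm strips
#'
#' The half-pitch stagger of the two 10 mm layers tiles the proximal
#' extent into strips of half a leaf width (the effective resolution of
#' the dual layer).  Each strip is covered by exactly one proximal pair
#' and, except for the two outermost strips, one distal pair.
#'
#' @param proxSpec,distSpec [MlcLayerSpec-class] for the two layers; the
#'   distal boundaries must sit half a leaf width off the proximal ones.
#' @return data.frame with columns `strip`, `y_low`, `y_high`,
#'   `prox_pair`, `dist_pair` (`NA` for the outermost strips).
#' @export
buildStrips <- function(proxSpec, distSpec) {
  w <- proxSpec@leafWidthIso
  if (distSpec@leafWidthIso != w)
    stop("layers must share the leaf width")
  if (proxSpec@nPairs != distSpec@nPairs + 1L)
    stop("stagger requires one more proximal pair than distal")
  if (abs(proxSpec@lateralOffset) > 1e-9 ||
      abs(distSpec@lateralOffset - w / 2) > 1e-9)
    stop("distal layer must be offset by half a leaf width (",
         w / 2, " mm), got ", distSpec@lateralOffset, " mm")
  half <- w / 2
  nStrips <- 2L * as.integer(proxSpec@nPairs)
  proxLow <- -proxSpec@nPairs * w / 2
  distLow <- -distSpec@nPairs * w / 2
  yLow <- proxLow + half * (seq_len(nStrips) - 1)
  s <- seq_len(nStrips)
  distPair <- floor((yLow - distLow) / w) + 1
  distPair[distPair < 1 | distPair > distSpec@nPairs] <- NA
  data.frame(
    strip = s,
    y_low = yLow,
    y_high = yLow + half,
    prox_pair = ceiling(s / 2),
    dist_pair = as.integer(distPair)
  )
}

#' Per-strip aperture geometry of one control point
#'
#' For each strip the effective gap is the intersection of the two layers'
#' pair openings, `max(0, min(x_B) - max(x_A))`.  Per bank, the trailing
#' distance is the separation of the two layers' same-bank tips and the
#' defining layer is the one whose tip is innermost (larger `x_A` on bank
#' A, smaller `x_B` on bank B); coincident tips are a tie with t = 0.
#' Tips are rounded to 0.01 mm before comparison so the t = 0 and t = 5 mm
#' class boundaries are decided exactly, not by float noise.  Strips
#' covered by the proximal layer only get their gap from that pair and no
#' trailing classification.
#'
#' @param cp a [ControlPoint-class].
#' @param strips output of [buildStrips()].
#' @return data.frame, one row per strip: `strip`, `dual`, `gap`, `tA`,
#'   `tB`, `defA`, `defB` (defining layer per bank: `"proximal"`,
#'   `"distal"` or `"tie"`; `NA` for proximal-only strips).
#' @export
stripApertures <- function(cp, strips) {
  pp <- round(cp@positions$proximal, 2)
  pd <- round(cp@positions$distal, 2)
  ip <- strips$prox_pair
  id <- strips$dist_pair
  dual <- !is.na(id)
  aP <- pp[ip, 1]; bP <- pp[ip, 2]
  aD <- bD <- rep(NA_real_, nrow(strips))
  aD[dual] <- pd[id[dual], 1]
  bD[dual] <- pd[id[dual], 2]

  gap <- ifelse(dual, pmax(0, pmin(bP, bD) - pmax(aP, aD)),
                pmax(0, bP - aP))
  # re-round the differences: 0.01 mm-rounded tips can still differ by
  # 4.9999... in floating point, which would misclassify the 5 mm bound
  tA <- ifelse(dual, round(abs(aP - aD), 2), NA_real_)
  tB <- ifelse(dual, round(abs(bP - bD), 2), NA_real_)
  defA <- ifelse(!dual, NA_character_,
                 ifelse(tA == 0, "tie",
                        ifelse(aP > aD, "proximal", "distal")))
  defB <- ifelse(!dual, NA_character_,
                 ifelse(tB == 0, "tie",
                        ifelse(bP < bD, "proximal", "distal")))
  data.frame(strip = strips$strip, dual = dual, gap = gap,
             tA = tA, tB = tB, defA = defA, defB = defB,
             stringsAsFactors = FALSE)
}

.TRAILING_CLASSES <- c("proximal_lt5", "proximal_ge5",
                       "distal_lt5", "distal_ge5", "overlap")

.classifyEdge <- function(def, t) {
  ifelse(t == 0, "overlap",
         paste0(def, ifelse(t < 5, "_lt5", "_ge5")))
}

#' Pooled gap-width and trailing statistics of a plan
#'
#' Pools every (control point, strip) sample with a positive effective gap
#' over all beams: gap percentiles over those samples, and the percentage
#' of bank edges (two per open dual-covered strip) in each of the five
#' trailing classes -- defining layer proximal or distal crossed with
#' 0 < t < 5 mm or t >= 5 mm, plus complete overlap (t = 0).  The classes
#' are exhaustive and mutually exclusive, so the percentages sum to 100.
#'
#' @param plan a [DualLayerPlan-class].
#' @param weighting `"unweighted"` (every control point counts equally) or
#'   `"mu_weighted"` (samples weighted by the control point's meterset
#'   increment times beam MU).
#' @return a [GapTrailingStats-class].
#' @export
planGapTrailingStats <- function(plan,
                                 weighting = c("unweighted",
                                               "mu_weighted")) {
  weighting <- match.arg(weighting)
  gaps <- numeric(0); gw <- numeric(0)
  cls <- character(0); cw <- numeric(0)
  for (beam in plan@beams) {
    strips <- buildStrips(beam@layerSpecs$proximal, beam@layerSpecs$distal)
    wts <- if (weighting == "mu_weighted")
      trapezoidWeights(metersetWeights(beam)) * beam@mu
    else rep(1, length(beam@controlPoints))
    for (k in seq_along(beam@controlPoints)) {
      if (wts[k] <= 0) next
      ap <- stripApertures(beam@controlPoints[[k]], strips)
      open <- ap$gap > 0
      if (!any(open)) next
      gaps <- c(gaps, ap$gap[open])
      gw <- c(gw, rep(wts[k], sum(open)))
      sel <- open & ap$dual
      if (any(sel)) {
        edges <- c(.classifyEdge(ap$defA[sel], ap$tA[sel]),
                   .classifyEdge(ap$defB[sel], ap$tB[sel]))
        cls <- c(cls, edges)
        cw <- c(cw, rep(wts[k], 2 * sum(sel)))
      }
    }
  }
  if (!length(gaps)) stop("empty aperture: plan has no open strips")
  q <- weightedQuantile(gaps, gw, c(0.25, 0.5, 0.75))
  names(q) <- c("p25", "median", "p75")
  pct <- vapply(.TRAILING_CLASSES,
                function(cl) 100 * sum(cw[cls == cl]) / sum(cw),
                numeric(1))
  new("GapTrailingStats", gapQuantiles = q, trailingPct = pct,
      nGaps = sum(gw), nEdges = sum(cw), weighting = weighting)
}

setMethod("show", "GapTrailingStats", function(object) {
  q <- object@gapQuantiles
  cat(sprintf("Gap width (mm): median %.1f [p25 %.1f, p75 %.1f]  (%s)\n",
              q["median"], q["p25"], q["p75"], object@weighting))
  cat("Trailing classes (% of open edges):\n")
  p <- object@trailingPct
  cat(sprintf("  proximal defining: %5.1f (0<t<5)  %5.1f (t>=5)\n",
              p["proximal_lt5"], p["proximal_ge5"]))
  cat(sprintf("  distal defining:   %5.1f (0<t<5)  %5.1f (t>=5)\n",
              p["distal_lt5"], p["distal_ge5"]))
  cat(sprintf("  complete overlap:  %5.1f (t=0)\n", p["overlap"]))
})

#' @describeIn planGapTrailingStats one-row data.frame of the statistics
#'   (Table-1-style columns), convenient for CSV reports.
#' @param x a [GapTrailingStats-class].
#' @param row.names,optional,... passed through for the S3 generic.
#' @export
as.data.frame.GapTrailingStats <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(
    gap_median = x@gapQuantiles[["median"]],
    gap_p25 = x@gapQuantiles[["p25"]],
    gap_p75 = x@gapQuantiles[["p75"]],
    pct_proximal_lt5 = x@trailingPct[["proximal_lt5"]],
    pct_proximal_ge5 = x@trailingPct[["proximal_ge5"]],
    pct_distal_lt5 = x@trailingPct[["distal_lt5"]],
    pct_distal_ge5 = x@trailingPct[["distal_ge5"]],
    pct_overlap = x@trailingPct[["overlap"]],
    weighting = x@weighting,
    row.names = row.names
  )
}
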