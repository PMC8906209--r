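# Independent brute-force gamma oracle: full lattice scan with its own
# interpolation code (linear-index trilinear on the flat dose vector),
# no pruning, no shared code with the package implementation beyond the
# gamma definition itself.

# Vectorized trilinear interpolation at an n x 3 position matrix.
bruteTrilinear <- function(axes, doseVec, P) {
  dims <- vapply(axes, length, 1L)
  n <- nrow(P)
  fr <- matrix(0, n, 3)
  i0 <- matrix(1L, n, 3)
  ok <- rep(TRUE, n)
  for (d in 1:3) {
    if (dims[d] == 1L) next
    f <- (P[, d] - axes[[d]][1]) / (axes[[d]][2] - axes[[d]][1])
    ok <- ok & f >= -1e-9 & f <= dims[d] - 1 + 1e-9
    f <- pmin(pmax(f, 0), dims[d] - 1)
    i0[, d] <- pmin(floor(f), dims[d] - 2) + 1L
    fr[, d] <- f - (i0[, d] - 1L)
  }
  strides <- c(1L, dims[1], dims[1] * dims[2])
  val <- numeric(n)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    corner <- c(cx, cy, cz)
    w <- rep(1, n)
    lin <- rep(1, n)
    for (d in 1:3) {
      if (corner[d] == 1 && dims[d] == 1L) { w <- 0; break }
      w <- w * if (corner[d]) fr[, d] else 1 - fr[, d]
      lin <- lin + (i0[, d] - 1L + corner[d]) * strides[d]
    }
    if (length(w) == 1 && all(w == 0)) next
    val <- val + w * doseVec[lin]
  }
  val[!ok] <- NA_real_
  val
}

bruteForceGamma <- function(measured, calculated, dosePct = 2, dtaMm = 2,
                            thresholdPct = 10, searchRadiusFactor = 3,
                            step = 0.2) {
  pts <- dosePoints(measured)
  meas <- doseValues(measured)
  dmax <- maxDose(measured)
  sel <- meas >= thresholdPct / 100 * dmax
  pts <- pts[sel, , drop = FALSE]
  meas <- meas[sel]
  axes <- calculated@axes
  dims <- vapply(axes, length, 1L)
  R <- searchRadiusFactor * dtaMm
  ks <- seq(-floor(R / step + 1e-9), floor(R / step + 1e-9)) * step
  off <- as.matrix(expand.grid(dx = if (dims[1] > 1) ks else 0,
                               dy = if (dims[2] > 1) ks else 0,
                               dz = if (dims[3] > 1) ks else 0))
  r2 <- rowSums(off^2)
  off <- off[r2 <= R^2 + 1e-9, , drop = FALSE]
  r2 <- r2[r2 <= R^2 + 1e-9]
  tol <- dosePct / 100 * dmax
  vapply(seq_along(meas), function(i) {
    P <- cbind(pts[i, 1] + off[, 1], pts[i, 2] + off[, 2],
               pts[i, 3] + off[, 3])
    dv <- bruteTrilinear(axes, calculated@dose, P)
    g2 <- r2 / dtaMm^2 + (dv - meas[i])^2 / tol^2
    sqrt(min(g2, na.rm = TRUE))
  }, numeric(1))
}
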