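# Internal numeric helpers.

# Round half-up (ties toward +Inf) at the given decimal resolution.
# Serialization uses 0.1 mm; a small relative guard absorbs binary
# representation error so e.g. 2.65 rounds to 2.7, not 2.6.
roundHalfUp <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9 * pmax(1, abs(x * s))) / s
}

# Per-control-point meterset increment weights (trapezoidal attribution of
# the delivery between consecutive control points).
trapezoidWeights <- function(w) {
  n <- length(w)
  if (n < 2L) return(rep(1, n))
  d <- diff(w)
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

# Weighted quantiles by linear interpolation of the weighted empirical CDF
# evaluated at midpoints (reduces to near type-7 behaviour for equal
# weights and large n).
weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

# Fractional coverage of the interval [u, v] by pixels centered at xc with
# width dx (vectorized over xc).
pixelCoverage <- function(xc, dx, u, v) {
  if (v <= u) return(numeric(length(xc)))
  pmax(0, pmin(v, xc + dx / 2) - pmax(u, xc - dx / 2)) / dx
}

# Bilinear interpolation on a regular grid; M is nx x ny, axes ax/ay
# uniformly spaced (either may have length 1 = constant axis).
bilinearGrid <- function(ax, ay, M, px, py) {
  nx <- length(ax)
  ny <- length(ay)
  fx <- if (nx > 1L) (px - ax[1]) / (ax[2] - ax[1]) else rep(0, length(px))
  fy <- if (ny > 1L) (py - ay[1]) / (ay[2] - ay[1]) else rep(0, length(py))
  if (any(fx < -1e-9 | fx > nx - 1 + 1e-9 |
          fy < -1e-9 | fy > ny - 1 + 1e-9))
    stop("interpolation point outside grid")
  fx <- pmin(pmax(fx, 0), nx - 1)
  fy <- pmin(pmax(fy, 0), ny - 1)
  i0 <- pmin(floor(fx), max(nx - 2, 0))
  j0 <- pmin(floor(fy), max(ny - 2, 0))
  tx <- fx - i0
  ty <- fy - j0
  i1 <- pmin(i0 + 1, nx - 1)
  j1 <- pmin(j0 + 1, ny - 1)
  idx <- function(i, j) M[cbind(i + 1, j + 1)]
  (1 - tx) * (1 - ty) * idx(i0, j0) +
    tx * (1 - ty) * idx(i1, j0) +
    (1 - tx) * ty * idx(i0, j1) +
    tx * ty * idx(i1, j1)
}

# Separable Gaussian blur of an nx x ny matrix sampled at spacing dx/dy.
# sigma in mm; zero-padded edges.
gaussianBlur2d <- function(M, dx, dy, sigma) {
  if (sigma <= 0) return(M)
  blur1 <- function(A, step) {
    r <- max(1L, ceiling(4 * sigma / step))
    k <- stats::dnorm(seq(-r, r) * step, sd = sigma)
    k <- k / sum(k)
    n <- nrow(A)
    out <- matrix(0, n, ncol(A))
    for (s in seq(-r, r)) {
      src <- seq_len(n) + s
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[s + r + 1] * A[src[ok], ]
    }
    out
  }
  t(blur1(t(blur1(M, dx)), dy))
}

# Derive a reproducible child seed (kept within 32-bit integer range).
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + k * 12289) %% .Machine$integer.max)
}
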