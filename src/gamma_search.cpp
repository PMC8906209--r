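#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multilinear interpolation on a regular grid stored x-fastest.
// Axes of length 1 are constant: the corresponding coordinate is ignored.
static inline double interpGrid(const double *dose,
                                const double *ax, int nx,
                                const double *ay, int ny,
                                const double *az, int nz,
                                double x, double y, double z,
                                bool &ok) {
  double fx = 0.0, fy = 0.0, fz = 0.0;
  int i0 = 0, j0 = 0, k0 = 0;
  if (nx > 1) {
    fx = (x - ax[0]) / (ax[1] - ax[0]);
    if (fx < -1e-9 || fx > nx - 1 + 1e-9) { ok = false; return 0.0; }
    if (fx < 0) fx = 0;
    if (fx > nx - 1) fx = nx - 1;
    i0 = (int)std::floor(fx); if (i0 > nx - 2) i0 = nx - 2;
    fx -= i0;
  }
  if (ny > 1) {
    fy = (y - ay[0]) / (ay[1] - ay[0]);
    if (fy < -1e-9 || fy > ny - 1 + 1e-9) { ok = false; return 0.0; }
    if (fy < 0) fy = 0;
    if (fy > ny - 1) fy = ny - 1;
    j0 = (int)std::floor(fy); if (j0 > ny - 2) j0 = ny - 2;
    fy -= j0;
  }
  if (nz > 1) {
    fz = (z - az[0]) / (az[1] - az[0]);
    if (fz < -1e-9 || fz > nz - 1 + 1e-9) { ok = false; return 0.0; }
    if (fz < 0) fz = 0;
    if (fz > nz - 1) fz = nz - 1;
    k0 = (int)std::floor(fz); if (k0 > nz - 2) k0 = nz - 2;
    fz -= k0;
  }
  ok = true;
  const int i1 = (nx > 1) ? i0 + 1 : i0;
  const int j1 = (ny > 1) ? j0 + 1 : j0;
  const int k1 = (nz > 1) ? k0 + 1 : k0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    const double wz = dk ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    const int kk = dk ? k1 : k0;
    for (int dj = 0; dj < 2; ++dj) {
      const double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      const int jj = dj ? j1 : j0;
      for (int di = 0; di < 2; ++di) {
        const double wx = di ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        const int ii = di ? i1 : i0;
        acc += wx * wy * wz * dose[ii * sx + jj * sy + kk * sz];
      }
    }
  }
  return acc;
}

// Gamma search over a precomputed offset lattice sorted by increasing
// distance.  off2norm holds r^2/dta^2 per offset; scanning in that order
// lets the loop stop as soon as the distance term alone exceeds the best
// gamma^2, which is exact on the lattice (the dose term is nonnegative).
// [[Rcpp::export]]
NumericVector gammaSearchCpp(NumericMatrix refPts, NumericVector refDose,
                             NumericVector ax, NumericVector ay,
                             NumericVector az, NumericVector dose,
                             NumericMatrix offsets, NumericVector off2norm,
                             NumericVector doseTol, LogicalVector covered,
                             bool prune) {
  const int n = refPts.nrow();
  const int m = offsets.nrow();
  const int nx = ax.size(), ny = ay.size(), nz = az.size();
  const double *pax = ax.begin(), *pay = ay.begin(), *paz = az.begin();
  const double *pd = dose.begin();
  NumericVector out(n, NA_REAL);

  for (int i = 0; i < n; ++i) {
    if (!covered[i]) continue;
    const double x0 = refPts(i, 0), y0 = refPts(i, 1), z0 = refPts(i, 2);
    const double dm = refDose[i];
    const double tol2 = doseTol[i] * doseTol[i];
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      const double dist2 = off2norm[k];
      if (prune && dist2 >= best) break;
      bool ok = true;
      const double dv = interpGrid(pd, pax, nx, pay, ny, paz, nz,
                                   x0 + offsets(k, 0),
                                   y0 + offsets(k, 1),
                                   z0 + offsets(k, 2), ok);
      if (!ok) continue;
      const double dd = dv - dm;
      const double g2 = dist2 + dd * dd / tol2;
      if (g2 < best) best = g2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
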