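#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a flattened column-major 3D array at a
// continuous 0-based voxel index. Returns false when the position falls
// outside the voxel-center bounding box.
static inline bool trilinear(const double *v, const int *n,
                             double cx, double cy, double cz, double &out) {
  if (cx < 0.0 || cy < 0.0 || cz < 0.0 ||
      cx > n[0] - 1 || cy > n[1] - 1 || cz > n[2] - 1)
    return false;
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
      z0 = (int)std::floor(cz);
  double fx = cx - x0, fy = cy - y0, fz = cz - z0;
  int x1 = x0 + 1 < n[0] ? x0 + 1 : n[0] - 1;
  int y1 = y0 + 1 < n[1] ? y0 + 1 : n[1] - 1;
  int z1 = z0 + 1 < n[2] ? z0 + 1 : n[2] - 1;
  long nx = n[0], nxy = (long)n[0] * n[1];
  out = (1 - fx) * (1 - fy) * (1 - fz) * v[x0 + nx * y0 + nxy * z0] +
             fx  * (1 - fy) * (1 - fz) * v[x1 + nx * y0 + nxy * z0] +
        (1 - fx) *      fy  * (1 - fz) * v[x0 + nx * y1 + nxy * z0] +
             fx  *      fy  * (1 - fz) * v[x1 + nx * y1 + nxy * z0] +
        (1 - fx) * (1 - fy) *      fz  * v[x0 + nx * y0 + nxy * z1] +
             fx  * (1 - fy) *      fz  * v[x1 + nx * y0 + nxy * z1] +
        (1 - fx) *      fy  *      fz  * v[x0 + nx * y1 + nxy * z1] +
             fx  *      fy  *      fz  * v[x1 + nx * y1 + nxy * z1];
  return true;
}

// Gamma index per reference voxel: minimum over the pre-computed spatial
// offsets (sorted by distance; distTerm = (r/dta)^2) of
// (doseDiff/doseTol)^2 + distTerm, square-rooted. The loop over offsets
// stops as soon as the distance term alone reaches the current best,
// which cannot change the minimum.
// [[Rcpp::export]]
NumericVector gamma_index_cpp(NumericVector ref, NumericVector ev,
                              IntegerVector dims, NumericVector spacing,
                              NumericMatrix offsets, NumericVector distTerm,
                              double doseTol, LogicalVector analyze) {
  const int nOff = offsets.nrow();
  int n[3] = {dims[0], dims[1], dims[2]};
  long total = (long)n[0] * n[1] * n[2];
  NumericVector gamma(total);
  const double *rv = REAL(ref), *evv = REAL(ev);
  const double *off = REAL(offsets);
  const double *dt = REAL(distTerm);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  for (long idx = 0; idx < total; ++idx) {
    if (!analyze[idx]) { gamma[idx] = NA_REAL; continue; }
    long rem = idx;
    int i = (int)(rem % n[0]); rem /= n[0];
    int j = (int)(rem % n[1]); rem /= n[1];
    int k = (int)rem;
    double xm = i * sx, ym = j * sy, zm = k * sz;
    double refDose = rv[idx];
    double best = R_PosInf;
    for (int m = 0; m < nOff; ++m) {
      if (dt[m] >= best) break;
      double cx = (xm + off[m]) / sx;
      double cy = (ym + off[m + nOff]) / sy;
      double cz = (zm + off[m + 2 * nOff]) / sz;
      double val;
      if (!trilinear(evv, n, cx, cy, cz, val)) continue;
      double dd = (val - refDose) / doseTol;
      double g2 = dd * dd + dt[m];
      if (g2 < best) best = g2;
    }
    gamma[idx] = std::sqrt(best);
  }
  return gamma;
}
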