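#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxelize a tube swept along a densely sampled curve: a voxel is foreground
// if its center lies within the local tube radius of any curve sample.
// curve: N x 3 (um), radius: N (um), origin: coordinate of voxel (1,1,1)
// center (um), voxel: edge length (um), dims: nx ny nz.
// [[Rcpp::export(name = ".voxelize_tube")]]
LogicalVector voxelize_tube(NumericMatrix curve, NumericVector radius,
                            NumericVector origin, double voxel,
                            IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int N = curve.nrow();
  for (int s = 0; s < N; ++s) {
    double cx = curve(s, 0), cy = curve(s, 1), cz = curve(s, 2);
    double r = radius[s], r2 = r * r;
    int i0 = std::max(0, (int)std::ceil((cx - r - origin[0]) / voxel));
    int i1 = std::min(nx - 1, (int)std::floor((cx + r - origin[0]) / voxel));
    int j0 = std::max(0, (int)std::ceil((cy - r - origin[1]) / voxel));
    int j1 = std::min(ny - 1, (int)std::floor((cy + r - origin[1]) / voxel));
    int k0 = std::max(0, (int)std::ceil((cz - r - origin[2]) / voxel));
    int k1 = std::min(nz - 1, (int)std::floor((cz + r - origin[2]) / voxel));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * voxel - cz, dz2 = dz * dz;
      if (dz2 > r2) continue;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * voxel - cy, dyz2 = dy * dy + dz2;
        if (dyz2 > r2) continue;
        double hw = std::sqrt(r2 - dyz2);
        int ia = std::max(i0, (int)std::ceil((cx - hw - origin[0]) / voxel));
        int ib = std::min(i1, (int)std::floor((cx + hw - origin[0]) / voxel));
        for (int i = ia; i <= ib; ++i)
          out[(R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}

// Trilinear interpolation of a logical 3D array at arbitrary points.
// Coordinates are in voxel-center units: point (0,0,0) is the center of
// voxel [1,1,1]. Points outside the grid evaluate to 0.
// [[Rcpp::export(name = ".trilinear_mask")]]
NumericVector trilinear_mask(LogicalVector v, IntegerVector dims,
                             NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < -1 || x > nx || y < -1 || y > ny || z < -1 || z > nz) { out[p] = 0; continue; }
    int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
    double fx = x - i, fy = y - j, fz = z - k;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk) for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        double val = v[(R_xlen_t)ii + nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk)] ? 1.0 : 0.0;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        acc += w * val;
      }
    out[p] = acc;
  }
  return out;
}
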