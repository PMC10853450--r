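#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 4-connected component labels of a logical matrix (0 = background).
// [[Rcpp::export(name = ".label_components_2d")]]
IntegerMatrix label_components_2d(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue< std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!m(i, j) || lab(i, j)) continue;
    lab(i, j) = ++next;
    q.push(std::make_pair(i, j));
    while (!q.empty()) {
      int ci = q.front().first, cj = q.front().second; q.pop();
      const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int ni = ci + di[k], nj = cj + dj[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (m(ni, nj) && !lab(ni, nj)) { lab(ni, nj) = next; q.push(std::make_pair(ni, nj)); }
      }
    }
  }
  return lab;
}

// Number of 6-connected foreground components of a logical 3D array.
// [[Rcpp::export(name = ".count_components_3d")]]
int count_components_3d(LogicalVector v, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> lab((size_t)nx * ny * nz, 0);
  int next = 0;
  std::queue<long long> q;
  auto idx = [&](int i, int j, int k) { return (long long)i + nx * ((long long)j + (long long)ny * k); };
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    long long p = idx(i, j, k);
    if (!v[p] || lab[p]) continue;
    lab[p] = ++next; q.push(p);
    while (!q.empty()) {
      long long c = q.front(); q.pop();
      int ci = (int)(c % nx), cj = (int)((c / nx) % ny), ck = (int)(c / ((long long)nx * ny));
      const int di[6] = {-1, 1, 0, 0, 0, 0}, dj[6] = {0, 0, -1, 1, 0, 0}, dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m2 = 0; m2 < 6; ++m2) {
        int ni = ci + di[m2], nj = cj + dj[m2], nk = ck + dk[m2];
        if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz) continue;
        long long np = idx(ni, nj, nk);
        if (v[np] && !lab[np]) { lab[np] = next; q.push(np); }
      }
    }
  }
  return next;
}
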