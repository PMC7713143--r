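#include <Rcpp.h>
#include <vector>

// 3-D connected-component labelling of a logical mask by breadth-first
// search. connectivity is 6 (face) or 26 (face+edge+corner).
// [[Rcpp::export]]
Rcpp::IntegerVector cc_label_3d(Rcpp::LogicalVector mask,
                                Rcpp::IntegerVector dims,
                                int connectivity = 6) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) Rcpp::stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    Rcpp::stop("connectivity must be 6 or 26");

  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }

  Rcpp::IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int y = rem / nx;
      int x = rem % nx;
      for (size_t k = 0; k < offx.size(); ++k) {
        int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[j] && !labels[j]) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}
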