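#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected component labelling of a 3-D logical array (iterative BFS).
// [[Rcpp::export]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int current = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++current;
    queue.clear();
    queue.push_back(s);
    lab[s] = current;
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && lab[w] == 0) { lab[w] = current; queue.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
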