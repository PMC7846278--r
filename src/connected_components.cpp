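#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a sparse voxel set in a (T, H, W) array.
// idx0: 0-based linear indices (column-major, t fastest) of foreground
// voxels; connectivity 6 (faces) or 26 (faces+edges+corners) in (t, y, x).
// Returns 1-based component ids aligned with idx0.
// [[Rcpp::export]]
IntegerVector label_sparse_components(IntegerVector idx0, IntegerVector dims,
                                      int connectivity) {
  const int T = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t n = idx0.size();
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::unordered_map<int, R_xlen_t> pos;
  pos.reserve(n * 2);
  for (R_xlen_t i = 0; i < n; ++i) pos.emplace(idx0[i], i);

  // neighbor offsets in (dt, dy, dx)
  std::vector<int> dt, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && (std::abs(a) + std::abs(b) + std::abs(c)) != 1)
          continue;
        dt.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nn = (int)dt.size();

  IntegerVector comp(n, 0);
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (comp[s] != 0) continue;
    ++next_label;
    comp[s] = next_label;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int lin = idx0[cur];
      int t = lin % T;
      int y = (lin / T) % H;
      int x = lin / (T * H);
      for (int k = 0; k < nn; ++k) {
        int t2 = t + dt[k], y2 = y + dy[k], x2 = x + dx[k];
        if (t2 < 0 || t2 >= T || y2 < 0 || y2 >= H || x2 < 0 || x2 >= W)
          continue;
        int lin2 = t2 + T * (y2 + H * x2);
        auto it = pos.find(lin2);
        if (it == pos.end()) continue;
        if (comp[it->second] == 0) {
          comp[it->second] = next_label;
          stack.push_back(it->second);
        }
      }
    }
  }
  return comp;
}
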