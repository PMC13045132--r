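#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 3x3 median with replicate padding at the borders, so the output value set
// is always a subset of the input value set (9 samples, odd count).

// [[Rcpp::export]]
NumericMatrix median3x3(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = std::min(std::max(c + dc, 0), nc - 1);
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = std::min(std::max(r + dr, 0), nr - 1);
          v[k++] = x(rr, cc);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(r, c) = v[4];
    }
  }
  return out;
}

// 4-connected component of `mask` containing (r0, c0), BFS. 0-based input.

// [[Rcpp::export]]
LogicalMatrix flood_component(LogicalMatrix mask, int r0, int c0) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  if (!mask(r0, c0)) return out;
  std::vector<int> stack;
  stack.push_back(r0 + c0 * nr);
  out(r0, c0) = true;
  const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    int r = i % nr, c = i / nr;
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) && !out(rr, cc)) {
        out(rr, cc) = true;
        stack.push_back(rr + cc * nr);
      }
    }
  }
  return out;
}
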