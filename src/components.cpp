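#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 8-connected component labeling of a binary raster by iterative flood fill.
// Input is a logical/integer matrix (row-major image convention, rows = y);
// output is an integer matrix with 0 for background and 1..k component ids,
// numbered in raster-scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components8_cpp(const LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = cr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
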