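// Dense image kernels: temporal rank filtering of a frame stack and
// 8-connected component labelling of a binary mask.

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>

using namespace Rcpp;

// arr has dim (nr, nc, nt).  For every pixel and frame the output is the
// rank-th smallest value over the temporal window [t - h, t + h], truncated
// at the ends of the sequence; the rank is capped at the truncated window
// length.
// [[Rcpp::export]]
NumericVector rank_filter_cpp(NumericVector arr, int nr, int nc, int nt,
                              int rank, int half_window) {
  NumericVector out(arr.size());
  int npix = nr * nc;
  std::vector<double> buf;
  buf.reserve(2 * half_window + 1);
  for (int t = 0; t < nt; ++t) {
    int t0 = std::max(0, t - half_window);
    int t1 = std::min(nt - 1, t + half_window);
    int len = t1 - t0 + 1;
    int k = std::min(rank, len) - 1;
    for (int p = 0; p < npix; ++p) {
      buf.clear();
      for (int s = t0; s <= t1; ++s) buf.push_back(arr[(R_xlen_t)s * npix + p]);
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out[(R_xlen_t)t * npix + p] = buf[k];
    }
  }
  out.attr("dim") = IntegerVector::create(nr, nc, nt);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push({r, c});
      while (!q.empty()) {
        auto [cr, cc] = q.front();
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int r2 = cr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              q.push({r2, c2});
            }
          }
        }
      }
    }
  }
  return lab;
}
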