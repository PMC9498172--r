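#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact k-th nearest-neighbour distances under the maximum (Chebyshev) norm.
// Brute force over all pairs; the point itself is excluded from its own
// neighbour list. Ties at the k-th order statistic are kept as-is (no
// jitter). Points are staged into a row-major buffer so the inner loop walks
// contiguous memory.
// [[Rcpp::export]]
NumericVector knn_linf_kth(NumericMatrix pts, int k) {
  const int n = pts.nrow(), d = pts.ncol();
  if (n < 2) stop("need at least two points");
  if (k < 1 || k > n - 1) stop("'k' must lie in [1, n-1]");

  std::vector<double> buf(static_cast<size_t>(n) * d);
  for (int c = 0; c < d; ++c) {
    const double* col = &pts(0, c);
    for (int i = 0; i < n; ++i) buf[static_cast<size_t>(i) * d + c] = col[i];
  }

  NumericVector out(n);
  std::vector<double> dst(n - 1);
  for (int i = 0; i < n; ++i) {
    const double* ri = &buf[static_cast<size_t>(i) * d];
    int m = 0;
    const double* rj = buf.data();
    for (int j = 0; j < n; ++j, rj += d) {
      if (j == i) continue;
      double dm = std::fabs(ri[0] - rj[0]);
      for (int c = 1; c < d; ++c) {
        double diff = std::fabs(ri[c] - rj[c]);
        if (diff > dm) dm = diff;
      }
      dst[m++] = dm;
    }
    std::nth_element(dst.begin(), dst.begin() + (k - 1), dst.end());
    out[i] = dst[k - 1];
  }
  return out;
}
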