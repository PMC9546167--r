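#include <Rcpp.h>
using namespace Rcpp;

// k-th nearest-neighbor Euclidean distance of each row of X within Y.
// Brute force: the sample sizes used here (<= 10^4) and dimensions (<= 8)
// make a spatial index unnecessary. Matrices are copied to row-major buffers
// so the inner loop is cache-friendly. When exclude_self is true, row i of X
// is assumed to coincide with row i of Y and is skipped (leave-one-out search
// within the same sample).

// [[Rcpp::export]]
NumericVector cpp_knn_kth_dist(NumericMatrix X, NumericMatrix Y, int k,
                               bool exclude_self) {
  int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("dimension mismatch between X and Y");
  int avail = exclude_self ? m - 1 : m;
  if (k < 1 || k > avail) stop("k must be between 1 and the number of available neighbors");
  std::vector<double> xr((size_t)n * d), yr((size_t)m * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) xr[(size_t)i * d + c] = X(i, c);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < d; ++c) yr[(size_t)j * d + c] = Y(j, c);
  NumericVector out(n);
  std::vector<double> best(k);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[(size_t)i * d];
    int filled = 0;
    double worst = R_PosInf;
    for (int j = 0; j < m; ++j) {
      if (exclude_self && j == i) continue;
      const double* yj = &yr[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = xi[c] - yj[c];
        s += diff * diff;
      }
      if (filled < k) {
        best[filled++] = s;
        if (filled == k) {
          std::make_heap(best.begin(), best.end());
          worst = best[0];
        }
      } else if (s < worst) {
        std::pop_heap(best.begin(), best.end());
        best[k - 1] = s;
        std::push_heap(best.begin(), best.end());
        worst = best[0];
      }
    }
    if (filled < k) stop("not enough neighbors");
    out[i] = std::sqrt(best[0]);
  }
  return out;
}
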