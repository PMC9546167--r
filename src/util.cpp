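#include <Rcpp.h>
using namespace Rcpp;

// column-wise cumulative sums (hot path of the h-function grid integration)

// [[Rcpp::export]]
NumericMatrix cpp_col_cumsum(NumericMatrix x) {
  int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      acc += x(i, j);
      out(i, j) = acc;
    }
  }
  return out;
}
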