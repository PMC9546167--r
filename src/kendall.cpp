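#include <Rcpp.h>
using namespace Rcpp;

// Tie-corrected Kendall tau-b by direct O(n^2) pair enumeration. Spike-count
// data are short (thousands of observations) and heavily tied, so the exact
// pair count is both affordable and the correct reference.

// [[Rcpp::export]]
double cpp_kendall_tau_b(NumericVector x, NumericVector y) {
  R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  double conc = 0.0, disc = 0.0, tx = 0.0, ty = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx == 0.0 && dy == 0.0) continue;
      if (dx == 0.0) { tx += 1.0; continue; }
      if (dy == 0.0) { ty += 1.0; continue; }
      if ((dx > 0.0) == (dy > 0.0)) conc += 1.0; else disc += 1.0;
    }
  }
  double den = std::sqrt((conc + disc + tx) * (conc + disc + ty));
  if (den == 0.0) stop("Kendall tau undefined: a variable is constant");
  return (conc - disc) / den;
}
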