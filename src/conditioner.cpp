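#include <Rcpp.h>
using namespace Rcpp;

// Fused conditioner network for coupling layers: scalar input -> one tanh
// hidden layer -> raw spline parameters -> constrained widths/heights (simplex
// with floor) and knot derivatives (softplus with floor, boundary fixed at 1).
// Forward caches everything the analytic backward pass needs.

static inline double softplus(double x) {
  return (x > 0 ? x : 0.0) + std::log1p(std::exp(-std::fabs(x)));
}

// [[Rcpp::export]]
List cpp_conditioner_forward(NumericVector a, NumericMatrix W1,
                             NumericVector b1, NumericMatrix W2,
                             NumericVector b2, int K, double min_bin,
                             double min_deriv, double deriv_raw_offset,
                             bool want_cache) {
  int n = a.size(), Hd = W1.ncol(), n_out = W2.ncol();
  if (n_out != 3 * K - 1) stop("conditioner output size mismatch");
  NumericMatrix W(n, K), Hm(n, K), D(n, K + 1);
  // cache matrices are only materialized when a backward pass will follow
  NumericMatrix Hh(want_cache ? n : 1, Hd), smW(want_cache ? n : 1, K),
      smH(want_cache ? n : 1, K), sig(want_cache ? n : 1, K - 1);
  std::vector<double> o(n_out), hh(Hd), sm(K);
  double scale = 1.0 - K * min_bin;
  for (int i = 0; i < n; ++i) {
    double ai = a[i];
    for (int h = 0; h < Hd; ++h) {
      hh[h] = std::tanh(ai * W1(0, h) + b1[h]);
      if (want_cache) Hh(i, h) = hh[h];
    }
    for (int j = 0; j < n_out; ++j) {
      double acc = b2[j];
      for (int h = 0; h < Hd; ++h) acc += hh[h] * W2(h, j);
      o[j] = acc;
    }
    // widths: softmax over o[0..K-1]
    double mx = o[0];
    for (int j = 1; j < K; ++j) if (o[j] > mx) mx = o[j];
    double s = 0.0;
    for (int j = 0; j < K; ++j) { sm[j] = std::exp(o[j] - mx); s += sm[j]; }
    for (int j = 0; j < K; ++j) {
      sm[j] /= s;
      W(i, j) = min_bin + scale * sm[j];
      if (want_cache) smW(i, j) = sm[j];
    }
    // heights: softmax over o[K..2K-1]
    mx = o[K];
    for (int j = 0; j < K; ++j) if (o[K + j] > mx) mx = o[K + j];
    s = 0.0;
    for (int j = 0; j < K; ++j) { sm[j] = std::exp(o[K + j] - mx); s += sm[j]; }
    for (int j = 0; j < K; ++j) {
      sm[j] /= s;
      Hm(i, j) = min_bin + scale * sm[j];
      if (want_cache) smH(i, j) = sm[j];
    }
    // derivatives: softplus over o[2K..3K-2] plus identity offset
    D(i, 0) = 1.0; D(i, K) = 1.0;
    for (int j = 0; j < K - 1; ++j) {
      double raw = o[2 * K + j] + deriv_raw_offset;
      D(i, j + 1) = min_deriv + softplus(raw);
      if (want_cache) sig(i, j) = 1.0 / (1.0 + std::exp(-raw));
    }
  }
  return List::create(_["W"] = W, _["H"] = Hm, _["D"] = D, _["Hh"] = Hh,
                      _["smW"] = smW, _["smH"] = smH, _["sig"] = sig);
}

// [[Rcpp::export]]
List cpp_conditioner_backward(NumericVector a, NumericMatrix W1,
                              NumericMatrix W2, NumericMatrix Hh,
                              NumericMatrix smW, NumericMatrix smH,
                              NumericMatrix sig, NumericMatrix gW,
                              NumericMatrix gH, NumericMatrix gD,
                              double min_bin) {
  int n = a.size(), Hd = W1.ncol(), K = gW.ncol(), n_out = 3 * K - 1;
  NumericMatrix gW1(1, Hd), gW2(Hd, n_out);
  NumericVector gb1(Hd), gb2(n_out), ga(n);
  std::vector<double> go(n_out), gHh(Hd);
  double scale = 1.0 - K * min_bin;
  for (int i = 0; i < n; ++i) {
    // softmax backward for widths and heights
    double dotW = 0.0, dotH = 0.0;
    for (int j = 0; j < K; ++j) {
      dotW += gW(i, j) * scale * smW(i, j);
      dotH += gH(i, j) * scale * smH(i, j);
    }
    for (int j = 0; j < K; ++j) {
      go[j] = smW(i, j) * (gW(i, j) * scale - dotW);
      go[K + j] = smH(i, j) * (gH(i, j) * scale - dotH);
    }
    for (int j = 0; j < K - 1; ++j)
      go[2 * K + j] = gD(i, j + 1) * sig(i, j);
    // linear output layer
    for (int h = 0; h < Hd; ++h) gHh[h] = 0.0;
    for (int j = 0; j < n_out; ++j) {
      double gj = go[j];
      gb2[j] += gj;
      for (int h = 0; h < Hd; ++h) {
        gW2(h, j) += Hh(i, h) * gj;
        gHh[h] += W2(h, j) * gj;
      }
    }
    // tanh hidden layer
    double gai = 0.0;
    for (int h = 0; h < Hd; ++h) {
      double gz = gHh[h] * (1.0 - Hh(i, h) * Hh(i, h));
      gW1(0, h) += a[i] * gz;
      gb1[h] += gz;
      gai += W1(0, h) * gz;
    }
    ga[i] = gai;
  }
  return List::create(_["gW1"] = gW1, _["gb1"] = gb1, _["gW2"] = gW2,
                      _["gb2"] = gb2, _["ga"] = ga);
}
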