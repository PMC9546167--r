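# Shared oracles and cached model fits for the test suite.

# brute-force tie-corrected Kendall tau (independent of the C++ path)
tau_b_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# exhaustive search for the largest subset with all pairwise |tau| > threshold
clique_bruteforce <- function(tau, threshold) {
  p <- nrow(tau)
  best <- integer(0)
  for (size in p:2) {
    combs <- utils::combn(p, size)
    for (c_i in seq_len(ncol(combs))) {
      s <- combs[, c_i]
      sub <- tau[s, s]
      if (all(sub[upper.tri(sub)] > threshold)) return(sort(s))
    }
  }
  integer(0)
}

# cache expensive flow fits shared between tests (training data and fit seeds
# are fixed; every consumer asserts a different property of the same study)
.fit_cache <- new.env(parent = emptyenv())

cached_pair_fit <- function(family, strength) {
  key <- paste(family, strength, sep = "_")
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  param <- switch(family, clayton = c(weak = 2, strong = 5),
                  frank = c(weak = 3, strong = 7),
                  gaussian = c(weak = 0.4, strong = 0.8))[[strength]]
  spec <- if (family == "gaussian") copula_spec(family, rho = param)
          else copula_spec(family, theta = param)
  uv <- copula_sample(spec, 5000, seed = 101)
  fl <- fit_flow(build_flow(list(n_layers = 3, hidden_units = 16, n_bins = 8,
                                 dim = 2), seed = 202), uv, seed = 303)
  out <- list(spec = spec, flow = fl, tau_true = copula_kendall_tau(spec))
  .fit_cache[[key]] <- out
  out
}
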