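# Information-theoretic estimators: Monte-Carlo copula entropy (in bits), a
# k-nearest-neighbor Kullback-Leibler divergence between sample sets (in
# nats), and empirical tie-corrected Kendall's tau.

#' Monte-Carlo copula entropy
#'
#' Estimates the differential entropy of a bivariate copula density,
#' `h = E[-log2 c(u1, u2)]`, by averaging over `K` draws from the model. The
#' negative of the copula entropy estimates the mutual information between the
#' two variables, independently of their margins.
#'
#' @param copula_model Either a [copula_spec()] or a trained 2D flow; anything
#'   exposing sampling and log-density works through these two classes.
#' @param K Number of Monte-Carlo samples (at least 100).
#' @param seed Integer seed.
#' @return An object of class `entropy_estimate` with fields `value` (bits),
#'   `K`, and `std_error` (sample standard deviation of the `-log2 c` terms
#'   divided by `sqrt(K)`).
#' @export
copula_entropy_mc <- function(copula_model, K = 8000, seed = 1L) {
  if (K < 100) stop("K must be at least 100")
  if (inherits(copula_model, "copula_spec")) {
    uv <- copula_sample(copula_model, K, seed = seed)
    terms <- -copula_log_pdf(copula_model, uv[, 1], uv[, 2]) / log(2)
  } else if (inherits(copula_model, "flow")) {
    if (copula_model$hyper$dim != 2) stop("copula entropy is defined for 2D models")
    uv <- .clamp01(flow_sample(copula_model, K, seed = seed))
    terms <- -flow_log_density(copula_model, uv) / log(2)
  } else stop("unsupported copula model")
  structure(list(value = mean(terms), K = K,
                 std_error = sd(terms) / sqrt(K)),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("copula entropy: %.4f bits (MC, K = %d, se = %.4f)\n",
              x$value, x$K, x$std_error))
  invisible(x)
}

#' k-nearest-neighbor Kullback-Leibler divergence between samples
#'
#' Estimates `D(P || Q)` from samples `X ~ P` (n x d) and `Y ~ Q` (m x d)
#' using k-th nearest-neighbor distances (Wang-Kulkarni-Verdu form):
#' `D = (d/n) sum_i log(nu_k(i) / rho_k(i)) + log(m / (n - 1))`, where
#' `rho_k(i)` is the distance from `X_i` to its k-th neighbor within `X`
#' (excluding itself) and `nu_k(i)` the k-th neighbor distance within `Y`.
#' Zero distances from duplicated points are floored at 1e-12.
#'
#' @param X Sample matrix from the first distribution.
#' @param Y Sample matrix from the second distribution.
#' @param k Neighbor order (default 5).
#' @return An object of class `kl_estimate` with the divergence in nats.
#' @export
kl_knn <- function(X, Y, k = 5) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- nrow(Y); d <- ncol(X)
  if (ncol(Y) != d) stop("X and Y must have the same dimension")
  if (n <= k || m <= k) stop("insufficient sample: need n, m > k")
  rho <- pmax(cpp_knn_kth_dist(X, X, k, TRUE), 1e-12)
  nu <- pmax(cpp_knn_kth_dist(X, Y, k, FALSE), 1e-12)
  val <- d / n * sum(log(nu / rho)) + log(m / (n - 1))
  structure(list(value = val, k = k, n = n, m = m, d = d),
            class = "kl_estimate")
}

#' @export
print.kl_estimate <- function(x, ...) {
  cat(sprintf("KL divergence: %.4f nats (kNN, k = %d, n = %d, m = %d, d = %d)\n",
              x$value, x$k, x$n, x$m, x$d))
  invisible(x)
}

#' Empirical Kendall's tau (tie-corrected)
#'
#' Computes the tau-b rank correlation by exact pair enumeration, with the
#' standard tie correction in the denominator. Spike-count data are heavily
#' tied, making the correction essential.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Kendall's tau-b in `[-1, 1]`.
#' @export
kendall_tau_empirical <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  cpp_kendall_tau_b(as.numeric(x), as.numeric(y))
}
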