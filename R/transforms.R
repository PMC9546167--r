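#' Fit an empirical margin
#'
#' Fits a marginal model from observed data. Discrete (integer-valued)
#' variables produce a frequency table holding the probability mass function,
#' the CDF `F(x) = Pr(X <= x)` and its left limit `F-(x) = Pr(X < x)`;
#' continuous variables produce a rank-based empirical CDF whose
#' pseudo-observations are `rank / (n + 1)`, keeping values strictly inside
#' the unit interval.
#'
#' @param x Numeric vector, length at least 2.
#' @param discrete Logical; if `NULL`, the variable is auto-flagged discrete
#'   when all values are integers and the number of distinct values is at most
#'   `sqrt(length(x))`.
#' @return An object of class `margin_table` (discrete) or `margin_ecdf`
#'   (continuous).
#' @export
fit_empirical_margin <- function(x, discrete = NULL) {
  if (length(x) < 2) stop("degenerate margin: need at least 2 observations")
  if (any(!is.finite(x))) stop("margin data must be finite")
  if (length(unique(x)) < 2) stop("degenerate margin: constant input")
  if (is.null(discrete)) discrete <- is_discrete(x)
  if (discrete) {
    if (any(x != round(x))) stop("discrete margin requires integer values")
    tab <- table(factor(x, levels = sort(unique(x))))
    support <- as.integer(names(tab))
    pmf <- as.numeric(tab) / length(x)
    cdf <- cumsum(pmf)
    cdf[length(cdf)] <- 1
    structure(list(support = support, pmf = pmf, cdf = cdf,
                   cdf_minus = c(0, head(cdf, -1)), n = length(x)),
              class = "margin_table")
  } else {
    structure(list(sorted = sort(x), n = length(x)), class = "margin_ecdf")
  }
}

#' Auto-detect whether a variable should be treated as discrete
#'
#' @param x Numeric vector.
#' @return `TRUE` when all values are integers and the number of distinct
#'   values is at most `sqrt(length(x))`.
#' @export
is_discrete <- function(x) {
  all(x == round(x)) && length(unique(x)) <= sqrt(length(x))
}

#' Distributional transform of discrete data
#'
#' Applies `G(x, V) = F-(x) + V (F(x) - F-(x))` with `V ~ U(0, 1)` i.i.d.,
#' turning a discrete variable into one that is marginally uniform on the unit
#' interval. Outputs are clamped to `[1e-6, 1 - 1e-6]` to keep downstream
#' log-densities finite.
#'
#' @param x Integer vector with all values in the margin's support.
#' @param margin A `margin_table` from [fit_empirical_margin()].
#' @param seed Integer seed for the jitter variables.
#' @return Numeric vector in the open unit interval.
#' @export
distributional_transform <- function(x, margin, seed = 1L) {
  if (!inherits(margin, "margin_table")) stop("margin must be a margin_table")
  idx <- match(x, margin$support)
  if (anyNA(idx)) stop("unknown category: value outside the margin's support")
  v <- .with_seed(seed, runif(length(x)))
  g <- margin$cdf_minus[idx] + v * (margin$cdf[idx] - margin$cdf_minus[idx])
  .clamp01(g)
}

#' Probability-integral transform
#'
#' Maps observations to pseudo-observations in the unit interval. Continuous
#' margins use the rank-based empirical CDF `r / (n + 1)` (mid-rank
#' interpolation for new values); discrete margins delegate to
#' [distributional_transform()].
#'
#' @param x Numeric vector.
#' @param margin A fitted margin from [fit_empirical_margin()].
#' @param seed Seed forwarded to the distributional transform for discrete
#'   margins.
#' @return Numeric vector strictly inside `(0, 1)`.
#' @export
probability_transform <- function(x, margin, seed = 1L) {
  if (inherits(margin, "margin_table"))
    return(distributional_transform(x, margin, seed = seed))
  if (!inherits(margin, "margin_ecdf")) stop("unknown margin type")
  s <- margin$sorted
  n <- margin$n
  # linear interpolation of order statistics at plotting positions r/(n+1):
  # training points map to their own rank/(n+1), new points interpolate,
  # so strictly increasing inputs stay strictly increasing inside the range
  .clamp01(approx(x = s, y = seq_len(n) / (n + 1), xout = x,
                  rule = 2, ties = max)$y)
}

#' Empirical quantile transform
#'
#' The generalized inverse of the fitted margin: continuous margins linearly
#' interpolate the order statistics at plotting positions `r / (n + 1)`;
#' discrete margins return the smallest support value whose CDF reaches `u`.
#'
#' @param margin A fitted margin.
#' @param u Probabilities in `(0, 1)`.
#' @return Values on the original data scale.
#' @export
margin_quantile <- function(margin, u) {
  if (inherits(margin, "margin_table")) {
    idx <- findInterval(u, margin$cdf, left.open = TRUE) + 1L
    idx <- pmin(idx, length(margin$support))
    return(margin$support[idx])
  }
  if (!inherits(margin, "margin_ecdf")) stop("unknown margin type")
  s <- margin$sorted
  n <- margin$n
  approx(x = seq_len(n) / (n + 1), y = s, xout = pmin(pmax(u, 1 / (n + 1)),
                                                      n / (n + 1)),
         rule = 2)$y
}

#' Uniform jitter of integer counts
#'
#' Returns `x + V` with `V ~ U[0, 1)` i.i.d., so that `floor` recovers the
#' original counts exactly. Used to make discrete variables pseudo-continuous.
#'
#' @param x Integer vector.
#' @param seed Integer seed.
#' @return Numeric vector with `floor(out) == x`.
#' @export
jitter_counts <- function(x, seed = 1L) {
  if (any(x != round(x))) stop("jitter_counts requires integer input")
  v <- .with_seed(seed, runif(length(x)))
  v[v >= 1] <- 1 - .Machine$double.eps
  x + v
}
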