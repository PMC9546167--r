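# Monotone rational-quadratic spline transforms on [0, 1].
#
# A spline is parameterized by K bin widths and K bin heights (positive,
# summing to 1) plus K - 1 interior knot derivatives (positive); the two
# boundary derivatives are fixed at 1 so the transform meets the identity at
# the corners of the unit square. Numerical floors keep every bin wider than
# MIN_BIN and every derivative above MIN_DERIV.

MIN_BIN <- 1e-3
MIN_DERIV <- 1e-3

#' Apply a rational-quadratic spline transform
#'
#' Evaluates the monotone piecewise rational-quadratic map defined by bin
#' widths, bin heights and interior knot derivatives (boundary derivatives are
#' fixed at 1), together with the log absolute derivative of the applied map.
#'
#' @param params A list with components `bin_widths` (K positive values
#'   summing to 1), `bin_heights` (likewise) and `knot_derivatives` (K - 1
#'   positive interior derivatives).
#' @param x Numeric vector in `[0, 1]`.
#' @param inverse If `TRUE`, apply the inverse map.
#' @return A list with `y` (transformed values) and `log_det`
#'   (`log |dy/dx|` of the applied map).
#' @examples
#' p <- list(bin_widths = rep(1/4, 4), bin_heights = rep(1/4, 4),
#'           knot_derivatives = rep(1, 3))
#' rq_spline_apply(p, c(0, 0.3, 1))  # identity map
#' @export
rq_spline_apply <- function(params, x, inverse = FALSE) {
  w <- params$bin_widths; h <- params$bin_heights; d <- params$knot_derivatives
  K <- length(w)
  if (length(h) != K || length(d) != K - 1)
    stop("invalid spline parameters: need K widths, K heights, K-1 derivatives")
  if (any(w <= 0) || any(h <= 0) || any(d <= 0))
    stop("invalid spline parameters: widths, heights and derivatives must be positive")
  if (abs(sum(w) - 1) > 1e-8 || abs(sum(h) - 1) > 1e-8)
    stop("invalid spline parameters: widths and heights must sum to 1")
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  W <- matrix(w, 1); H <- matrix(h, 1); D <- matrix(c(1, d, 1), 1)
  if (inverse) {
    r <- cpp_rqs_inverse(x, W, H, D)
    list(y = r$x, log_det = -r$logdet)
  } else {
    r <- cpp_rqs_forward(x, W, H, D)
    list(y = r$y, log_det = r$logdet)
  }
}

# --- internal parameter constraints and their backward passes ---------------

.row_max <- function(a) {
  m <- a[, 1]
  for (j in seq_len(ncol(a))[-1]) m <- pmax(m, a[, j])
  m
}

.softmax_rows <- function(a) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  e <- exp(a - .row_max(a))
  e / rowSums(e)
}

# raw (unconstrained) widths/heights -> simplex with floor MIN_BIN
.constrain_bins <- function(a) {
  sm <- .softmax_rows(a)
  K <- ncol(sm)
  list(value = MIN_BIN + (1 - K * MIN_BIN) * sm, sm = sm)
}

.constrain_bins_bwd <- function(cache, g) {
  sm <- cache$sm
  K <- ncol(sm)
  gsm <- (1 - K * MIN_BIN) * g
  sm * (gsm - rowSums(gsm * sm))
}

# raw interior derivatives -> positive with floor MIN_DERIV; boundaries = 1
.constrain_derivs <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, 1)
  sp <- .softplus(b)
  n <- nrow(b)
  list(value = cbind(rep(1, n), MIN_DERIV + sp, rep(1, n)),
       sig = 1 / (1 + exp(-b)))
}

.constrain_derivs_bwd <- function(cache, gD) {
  K1 <- ncol(gD)
  gD[, 2:(K1 - 1), drop = FALSE] * cache$sig
}

# raw derivative offset such that a zero raw parameter yields derivative 1
.DERIV_RAW_ID <- NULL
.deriv_raw_identity <- function() .softplus_inv(1 - MIN_DERIV)
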