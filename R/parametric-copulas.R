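#' Specify a parametric bivariate copula
#'
#' Constructs a validated specification of a closed-form bivariate copula.
#' These families serve as simulation ground truth and as analytic oracles:
#' Clayton (lower-tail dependent, parameter `theta > 0`), Frank (radially
#' symmetric, `theta != 0`), Gaussian (elliptical, correlation `-1 < rho < 1`)
#' and the independence copula (no parameter).
#'
#' @param family One of `"clayton"`, `"frank"`, `"gaussian"`,
#'   `"independence"`.
#' @param theta Dependence parameter for Clayton or Frank.
#' @param rho Off-diagonal correlation for the Gaussian copula.
#' @return An object of class `copula_spec`.
#' @examples
#' copula_spec("clayton", theta = 2)
#' copula_spec("gaussian", rho = 0.8)
#' @export
copula_spec <- function(family = c("clayton", "frank", "gaussian", "independence"),
                        theta = NULL, rho = NULL) {
  family <- match.arg(family)
  if (family == "clayton") {
    if (is.null(theta) || !is.null(rho) || theta <= 0)
      stop("invalid copula spec: clayton requires theta > 0 and no rho")
  } else if (family == "frank") {
    if (is.null(theta) || !is.null(rho) || theta == 0)
      stop("invalid copula spec: frank requires theta != 0 and no rho")
  } else if (family == "gaussian") {
    if (is.null(rho) || !is.null(theta) || abs(rho) >= 1)
      stop("invalid copula spec: gaussian requires -1 < rho < 1 and no theta")
  } else {
    if (!is.null(theta) || !is.null(rho))
      stop("invalid copula spec: independence takes no parameter")
  }
  structure(list(family = family, theta = theta, rho = rho),
            class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  par <- if (!is.null(x$theta)) sprintf("theta = %g", x$theta)
         else if (!is.null(x$rho)) sprintf("rho = %g", x$rho) else ""
  cat(sprintf("<copula_spec> %s %s\n", x$family, par))
  invisible(x)
}

.check_spec <- function(spec) {
  if (!inherits(spec, "copula_spec")) stop("not a copula_spec")
  spec
}

#' Copula cumulative distribution function
#'
#' Evaluates `C(u, v)` for a parametric copula. The Gaussian copula CDF is
#' computed by one-dimensional Gauss quadrature of the conditional normal
#' probability; the others use their closed forms.
#'
#' @param spec A [copula_spec()].
#' @param u,v Numeric vectors in `[0, 1]` (recycled to common length).
#' @return Numeric vector of copula probabilities.
#' @export
copula_cdf <- function(spec, u, v) {
  .check_spec(spec)
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1)) stop("u, v must lie in [0, 1]")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  out <- switch(spec$family,
    independence = u * v,
    clayton = {
      th <- spec$theta
      pmax(u^(-th) + v^(-th) - 1, 0)^(-1 / th)
    },
    frank = {
      th <- spec$theta
      -log1p(expm1(-th * u) * expm1(-th * v) / expm1(-th)) / th
    },
    gaussian = .gauss_cdf(u, v, spec$rho)
  )
  # uniform-margin boundaries, exactly
  out[u == 0 | v == 0] <- 0
  out[v == 1] <- u[v == 1]
  out[u == 1] <- v[u == 1]
  pmin(pmax(out, 0), 1)
}

# C(u,v) = int_{-inf}^{qnorm(u)} dnorm(t) * pnorm((qnorm(v) - rho t)/sqrt(1-rho^2)) dt
.gauss_cdf <- function(u, v, rho) {
  gl <- .gauss_legendre(96)
  vapply(seq_along(u), function(i) {
    if (u[i] <= 0 || v[i] <= 0) return(0)
    if (u[i] >= 1) return(v[i])
    if (v[i] >= 1) return(u[i])
    a <- qnorm(u[i]); b <- qnorm(v[i])
    lo <- -8.5; hi <- a
    t <- (gl$nodes + 1) / 2 * (hi - lo) + lo
    w <- gl$weights * (hi - lo) / 2
    sum(w * dnorm(t) * pnorm((b - rho * t) / sqrt(1 - rho^2)))
  }, numeric(1))
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
.gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * (e$vectors[1, idx])^2)
}

#' Copula density
#'
#' Evaluates the copula density `c(u, v)` in the open unit square.
#'
#' @inheritParams copula_cdf
#' @return Numeric vector of nonnegative densities.
#' @export
copula_pdf <- function(spec, u, v) {
  .check_spec(spec)
  if (any(u <= 0 | u >= 1) || any(v <= 0 | v >= 1))
    stop("u, v must lie strictly inside (0, 1)")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  switch(spec$family,
    independence = rep(1, n),
    clayton = {
      th <- spec$theta
      (1 + th) * (u * v)^(-th - 1) * (u^(-th) + v^(-th) - 1)^(-1 / th - 2)
    },
    frank = {
      th <- spec$theta
      num <- th * (-expm1(-th)) * exp(-th * (u + v))
      den <- (-expm1(-th)) - (-expm1(-th * u)) * (-expm1(-th * v))
      num / den^2
    },
    gaussian = {
      rho <- spec$rho
      a <- qnorm(u); b <- qnorm(v)
      exp(-(rho^2 * (a^2 + b^2) - 2 * rho * a * b) / (2 * (1 - rho^2))) /
        sqrt(1 - rho^2)
    })
}

#' Conditional h-function of a parametric copula
#'
#' Computes `h(u | v) = dC(u, v) / dv`, the conditional CDF of `U` given
#' `V = v`. This is the workhorse of vine tree propagation and of
#' inverse-Rosenblatt sampling.
#'
#' @inheritParams copula_cdf
#' @return Numeric vector of conditional probabilities.
#' @export
copula_hfunc <- function(spec, u, v) {
  .check_spec(spec)
  if (any(v <= 0 | v >= 1)) stop("v must lie strictly inside (0, 1)")
  n <- max(length(u), length(v))
  u <- rep_len(pmin(pmax(u, 0), 1), n); v <- rep_len(v, n)
  switch(spec$family,
    independence = u,
    clayton = {
      th <- spec$theta
      out <- v^(-th - 1) * pmax(u^(-th) + v^(-th) - 1, 0)^(-1 / th - 1)
      out[u == 0] <- 0; out[u == 1] <- 1
      out
    },
    frank = {
      th <- spec$theta
      A <- expm1(-th * u); B <- expm1(-th * v); Dd <- expm1(-th)
      out <- A * exp(-th * v) / (Dd + A * B)
      out[u == 0] <- 0; out[u == 1] <- 1
      out
    },
    gaussian = {
      rho <- spec$rho
      out <- pnorm((qnorm(u) - rho * qnorm(v)) / sqrt(1 - rho^2))
      out[u == 0] <- 0; out[u == 1] <- 1
      out
    })
}

#' Inverse conditional h-function
#'
#' Solves `h(u | v) = p` for `u`. Closed forms exist for all four families;
#' a safeguarded bisection fallback guarantees the round trip
#' `h(h^{-1}(p | v) | v) = p` to 1e-8 if a closed form ever leaves the unit
#' interval.
#'
#' @param spec A [copula_spec()].
#' @param p Target conditional probabilities in `(0, 1)`.
#' @param v Conditioning values in `(0, 1)`.
#' @return Numeric vector of `u` values in `(0, 1)`.
#' @export
copula_hinv <- function(spec, p, v) {
  .check_spec(spec)
  if (any(p <= 0 | p >= 1) || any(v <= 0 | v >= 1))
    stop("p, v must lie strictly inside (0, 1)")
  n <- max(length(p), length(v))
  p <- rep_len(p, n); v <- rep_len(v, n)
  out <- switch(spec$family,
    independence = p,
    clayton = {
      th <- spec$theta
      ((p * v^(th + 1))^(-th / (th + 1)) - v^(-th) + 1)^(-1 / th)
    },
    frank = {
      th <- spec$theta
      B <- expm1(-th * v); Dd <- expm1(-th)
      A <- p * Dd / (exp(-th * v) - p * B)
      -log1p(A) / th
    },
    gaussian = {
      rho <- spec$rho
      pnorm(rho * qnorm(v) + sqrt(1 - rho^2) * qnorm(p))
    })
  bad <- !is.finite(out) | out <= 0 | out >= 1
  if (any(bad)) out[bad] <- .hinv_bisect(spec, p[bad], v[bad])
  out
}

.hinv_bisect <- function(spec, p, v) {
  vapply(seq_along(p), function(i) {
    lo <- 1e-10; hi <- 1 - 1e-10
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (copula_hfunc(spec, mid, v[i]) < p[i]) lo <- mid else hi <- mid
      if (hi - lo < 1e-12) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Sample from a parametric copula
#'
#' Draws `n` points from the copula by the conditional-inverse method:
#' `v ~ U(0,1)`, `p ~ U(0,1)`, `u = h^{-1}(p | v)`.
#'
#' @param spec A [copula_spec()].
#' @param n Number of samples.
#' @param seed Integer seed for reproducibility.
#' @return An `n x 2` matrix of points in the unit square.
#' @export
copula_sample <- function(spec, n, seed = 1L) {
  .check_spec(spec)
  stopifnot(n >= 1)
  .with_seed(seed, {
    v <- .clamp01(runif(n))
    p <- .clamp01(runif(n))
    u <- copula_hinv(spec, p, v)
    cbind(u = .clamp01(u), v = v)
  })
}

#' Closed-form Kendall's tau of a parametric copula
#'
#' Clayton: `theta / (theta + 2)`; Gaussian: `(2/pi) asin(rho)`; Frank:
#' `1 - 4/theta (1 - D1(theta))` with the first Debye function computed by
#' numeric quadrature; independence: 0.
#'
#' @param spec A [copula_spec()].
#' @return Kendall's tau.
#' @export
copula_kendall_tau <- function(spec) {
  .check_spec(spec)
  switch(spec$family,
    independence = 0,
    clayton = spec$theta / (spec$theta + 2),
    gaussian = 2 / pi * asin(spec$rho),
    frank = {
      th <- spec$theta
      debye1 <- integrate(function(t) t / expm1(t), 0, abs(th),
                          rel.tol = 1e-10)$value / abs(th)
      tau <- 1 - 4 / abs(th) * (1 - debye1)
      if (th < 0) -tau else tau
    })
}

#' Log-density of a parametric copula
#'
#' @inheritParams copula_pdf
#' @return Numeric vector of log densities.
#' @export
copula_log_pdf <- function(spec, u, v) log(copula_pdf(spec, u, v))

# JSON (de)serialization of specs -------------------------------------------

#' @rdname copula_spec
#' @param x A `copula_spec` (for `copula_spec_to_json`) or JSON string.
#' @export
copula_spec_to_json <- function(x) {
  .check_spec(x)
  jsonlite::toJSON(Filter(Negate(is.null), unclass(x)), auto_unbox = TRUE)
}

#' @rdname copula_spec
#' @param json JSON text produced by `copula_spec_to_json`.
#' @export
copula_spec_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  copula_spec(o$family, theta = o$theta, rho = o$rho)
}
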