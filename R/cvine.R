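# Canonical vine (C-vine) pair-copula construction with spline-flow pair
# copulas. The joint density factorizes into d margins and d(d-1)/2 bivariate
# (conditional) copulas; tree j pairs the j-th root variable with every later
# variable, conditionally on the first j-1 roots, under the simplifying
# assumption (conditional copulas depend on conditioning variables only
# through the conditional CDFs propagated by h-functions).

#' Order variables for the C-vine
#'
#' Variables are sorted by decreasing total absolute Kendall's tau with all
#' other variables, so the most strongly connected variable becomes the root
#' of the first tree. Ties break deterministically by original column index.
#'
#' @param u Matrix of pseudo-observations (rows are observations).
#' @return An integer permutation of the column indices.
#' @export
order_variables <- function(u) {
  u <- as.matrix(u)
  d <- ncol(u)
  if (nrow(u) < 10 || d < 2) stop("need at least 10 rows and 2 columns")
  tau <- matrix(0, d, d)
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    tau[i, j] <- tau[j, i] <- abs(kendall_tau_empirical(u[, i], u[, j]))
  }
  totals <- rowSums(tau)
  order(-totals, seq_len(d))
}

.grid_n <- 256L  # integration intervals for flow h-functions

# conditional CDF values of a 2D copula flow on the uniform grid, one column
# per conditioning value; returns the normalized cumulative (257 x length(v))
.flow_cond_cum <- function(copula_flow, v, chunk = 2048L) {
  g <- seq(0, 1, length.out = .grid_n + 1L)
  out <- matrix(0, .grid_n + 1L, length(v))
  for (s in seq(1, length(v), by = chunk)) {
    cols <- s:min(s + chunk - 1L, length(v))
    pts <- cbind(rep(g, times = length(cols)),
                 rep(v[cols], each = length(g)))
    dens <- matrix(exp(flow_log_density(copula_flow, pts)),
                   nrow = length(g))
    steps <- (dens[-1L, , drop = FALSE] + dens[-(.grid_n + 1L), , drop = FALSE]) /
      (2 * .grid_n)
    cum <- rbind(0, cpp_col_cumsum(steps))
    out[, cols] <- sweep(cum, 2, cum[.grid_n + 1L, ], "/")
  }
  out
}

#' Conditional h-function of a fitted copula flow
#'
#' Computes `h(u | v) = dC(u, v) / dv`, the conditional CDF of the first
#' coordinate given the second, by numeric integration of the flow density on
#' a fixed 256-interval grid (trapezoid rule, normalized per conditioning
#' value so that `h(1 | v) = 1` exactly).
#'
#' @param copula_flow A trained 2D flow.
#' @param u Values of the dependent coordinate, in `[0, 1]`.
#' @param v Conditioning values in `(0, 1)` (recycled against `u`).
#' @return Conditional probabilities in `[0, 1]`.
#' @export
vine_hfunc <- function(copula_flow, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  cum <- .flow_cond_cum(copula_flow, v)
  pos <- pmin(pmax(u, 0), 1) * .grid_n
  i0 <- pmin(floor(pos), .grid_n - 1L)
  frac <- pos - i0
  idx <- cbind(i0 + 1L, seq_len(n))
  lo <- cum[idx]
  hi <- cum[cbind(i0 + 2L, seq_len(n))]
  lo + frac * (hi - lo)
}

#' Inverse conditional h-function of a fitted copula flow
#'
#' Solves `h(u | v) = p` for `u` by inverting the piecewise-linear conditional
#' CDF built on the same fixed grid used by [vine_hfunc()].
#'
#' @param copula_flow A trained 2D flow.
#' @param p Conditional probabilities in `(0, 1)`.
#' @param v Conditioning values in `(0, 1)`.
#' @return Values of the dependent coordinate in `(0, 1)`.
#' @export
vine_hinv <- function(copula_flow, p, v) {
  n <- max(length(p), length(v))
  p <- rep_len(p, n); v <- rep_len(v, n)
  cum <- .flow_cond_cum(copula_flow, v)
  out <- numeric(n)
  for (j in seq_len(n)) {
    cj <- cum[, j]
    i0 <- findInterval(p[j], cj, all.inside = TRUE)
    denom <- cj[i0 + 1L] - cj[i0]
    frac <- if (denom > 0) (p[j] - cj[i0]) / denom else 0.5
    out[j] <- (i0 - 1L + frac) / .grid_n
  }
  .clamp01(out)
}

#' Default C-vine fitting configuration
#'
#' @param margin_method `"flow"` fits a 1D spline flow to each continuous
#'   margin (required for [vine_log_density()] on continuous data);
#'   `"empirical"` keeps rank-based empirical margins only. Discrete margins
#'   always use the empirical frequency table.
#' @param hyper Pair-copula flow hyperparameters used when `n_trials = 1`.
#' @param n_trials Number of random-search trials per pair copula (1 = fit the
#'   single `hyper` configuration).
#' @param search_space Candidate grids for the random search.
#' @param train Training configuration overrides (see [flow_train_config()]).
#' @param jitter_replicates Distributional-transform replicates averaged in
#'   [vine_log_density()] for discrete columns.
#' @param ordering Optional fixed variable ordering (permutation of column
#'   indices); `NULL` (default) orders data-driven via [order_variables()].
#'   Fixing the ordering is appropriate when the vine structure is known, as
#'   in simulation benchmarks.
#' @return A list of settings for [fit_cvine()].
#' @export
cvine_fit_config <- function(margin_method = c("flow", "empirical"),
                             hyper = list(n_layers = 3, hidden_units = 16,
                                          n_bins = 8),
                             n_trials = 1,
                             search_space = list(n_layers = c(1, 2, 3),
                                                 hidden_units = c(16, 32, 64, 128),
                                                 n_bins = c(4, 8, 16, 32)),
                             train = list(), jitter_replicates = 10,
                             ordering = NULL) {
  list(margin_method = match.arg(margin_method), hyper = hyper,
       n_trials = n_trials, search_space = search_space, train = train,
       jitter_replicates = jitter_replicates, ordering = ordering)
}

#' Fit a C-vine of spline-flow pair copulas
#'
#' Implements the Inference-for-Margins pipeline: (1) fit each margin
#' (empirical table for discrete columns, optionally a 1D spline flow for
#' continuous columns); (2) map data to pseudo-observations (rank/(n+1) for
#' continuous columns, distributional transform for discrete ones); (3) order
#' variables by total absolute Kendall's tau; (4) fit the pair copulas tree by
#' tree, propagating conditional pseudo-observations with h-functions
#' evaluated on the just-fitted copulas, under the simplifying assumption.
#'
#' @param data Numeric matrix or data frame (observations x variables).
#' @param column_types Optional character vector (`"continuous"` /
#'   `"discrete"`) per column; `NULL` auto-detects (integer values with at
#'   most `sqrt(n)` distinct levels are flagged discrete).
#' @param fit_cfg A list from [cvine_fit_config()]; partial lists are merged.
#' @param seed Integer root seed for all randomness (transforms, training).
#' @return An object of class `cvine`.
#' @export
fit_cvine <- function(data, column_types = NULL, fit_cfg = list(), seed = 1L) {
  user_hyper <- "hyper" %in% names(fit_cfg)
  cfg <- utils::modifyList(cvine_fit_config(), fit_cfg)
  x <- as.matrix(data)
  n <- nrow(x); d <- ncol(x)
  if (n < 100) stop("need at least 100 observations")
  if (d < 2) stop("need at least 2 variables")
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("V", seq_len(d))

  if (is.null(column_types)) {
    discrete <- vapply(seq_len(d), function(k) is_discrete(x[, k]), logical(1))
  } else {
    if (length(column_types) != d) stop("column_types length mismatch")
    discrete <- column_types == "discrete"
  }
  # distributional-transform copulas of low-count data are piecewise-constant
  # blocks; finer splines resolve the block edges noticeably better
  if (!user_hyper && any(discrete)) cfg$hyper$n_bins <- 16

  margins <- vector("list", d)
  u <- matrix(0, n, d)
  for (k in seq_len(d)) {
    emp <- fit_empirical_margin(x[, k], discrete = discrete[k])
    mflow <- NULL
    if (!discrete[k] && cfg$margin_method == "flow") {
      mflow <- fit_margin_flow(x[, k], train_cfg = cfg$train,
                               seed = .child_seed(seed, paste0("margin", k)))
    }
    margins[[k]] <- list(empirical = emp, flow = mflow, discrete = discrete[k])
    u[, k] <- probability_transform(x[, k], emp,
                                    seed = .child_seed(seed, paste0("dt", k)))
  }

  ordering <- if (is.null(cfg$ordering)) order_variables(u)
              else as.integer(cfg$ordering)
  if (!identical(sort(ordering), seq_len(d)))
    stop("ordering must be a permutation of the column indices")
  v <- u[, ordering, drop = FALSE]

  pair_copulas <- vector("list", d - 1)
  diag_rows <- list()
  for (j in seq_len(d - 1)) {
    m <- d - j + 1L  # columns still in play; column 1 is the tree-j root
    pair_copulas[[j]] <- vector("list", m - 1L)
    for (i in 2:m) {
      dat <- .clamp01(cbind(v[, i], v[, 1]))
      fit_seed <- .child_seed(seed, sprintf("tree%d_pair%d", j, i - 1))
      fl <- tryCatch({
        if (cfg$n_trials > 1) {
          flow_random_search(dat, dim = 2, search_space = cfg$search_space,
                             n_trials = cfg$n_trials, seed = fit_seed,
                             train_cfg = cfg$train)
        } else {
          hy <- cfg$hyper; hy$dim <- 2L
          fit_flow(build_flow(hy, seed = fit_seed), dat,
                   train_cfg = cfg$train, seed = fit_seed)
        }
      }, error = function(e)
        stop(sprintf("pair copula fit failed at tree %d, pair %d: %s",
                     j, i - 1, conditionMessage(e))))
      pair_copulas[[j]][[i - 1L]] <- fl
      diag_rows[[length(diag_rows) + 1L]] <-
        data.frame(tree = j, pair = i - 1L, val_ll = fl$best_val_ll,
                   n_layers = fl$hyper$n_layers, n_bins = fl$hyper$n_bins,
                   hidden_units = fl$hyper$hidden_units)
    }
    if (j < d - 1) {
      vnew <- matrix(0, n, m - 1L)
      for (i in 2:m) {
        vnew[, i - 1L] <- vine_hfunc(pair_copulas[[j]][[i - 1L]],
                                     v[, i], v[, 1])
      }
      v <- .clamp01(vnew)
    }
  }

  structure(list(ordering = ordering, margins = margins, discrete = discrete,
                 pair_copulas = pair_copulas,
                 fit_diagnostics = do.call(rbind, diag_rows),
                 d = d, n = n, var_names = cn, seed = as.integer(seed),
                 fit_cfg = cfg),
            class = "cvine")
}

#' @export
print.cvine <- function(x, ...) {
  cat(sprintf("<cvine> d=%d, n=%d, %d pair copulas, ordering: %s\n",
              x$d, x$n, x$d * (x$d - 1) / 2,
              paste(x$var_names[x$ordering], collapse = " > ")))
  invisible(x)
}

# pseudo-observations of new data under the vine's fitted margins
.vine_pseudo_obs <- function(vine, x, seed) {
  d <- vine$d
  u <- matrix(0, nrow(x), d)
  for (k in seq_len(d)) {
    u[, k] <- probability_transform(x[, k], vine$margins[[k]]$empirical,
                                    seed = .child_seed(seed, paste0("dt", k)))
  }
  u
}

# sum of pair-copula log densities for one pseudo-observation replicate
.vine_copula_log_density_u <- function(vine, u) {
  v <- .clamp01(u[, vine$ordering, drop = FALSE])
  d <- vine$d
  total <- numeric(nrow(u))
  for (j in seq_len(d - 1)) {
    m <- d - j + 1L
    for (i in 2:m) {
      total <- total + flow_log_density(vine$pair_copulas[[j]][[i - 1L]],
                                        cbind(v[, i], v[, 1]))
    }
    if (j < d - 1) {
      vnew <- matrix(0, nrow(u), m - 1L)
      for (i in 2:m) {
        vnew[, i - 1L] <- vine_hfunc(vine$pair_copulas[[j]][[i - 1L]],
                                     v[, i], v[, 1])
      }
      v <- .clamp01(vnew)
    }
  }
  total
}

#' Joint log-density under a fitted C-vine
#'
#' Sums the margin log-densities (spline-flow density for continuous margins,
#' empirical pmf for discrete ones) and the pair-copula log-densities, with
#' conditional arguments rebuilt by the same h-function recursion used during
#' fitting. For discrete columns the copula term is averaged (on the density
#' scale) over seeded distributional-transform jitter replicates.
#'
#' @param vine A fitted `cvine`.
#' @param x Matrix of observations matching the training columns.
#' @param seed Seed for the distributional-transform jitter.
#' @return Numeric vector of log densities.
#' @export
vine_log_density <- function(vine, x, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) != vine$d) stop("dimension mismatch with the fitted vine")
  n <- nrow(x)
  marg <- numeric(n)
  for (k in seq_len(vine$d)) {
    mk <- vine$margins[[k]]
    if (mk$discrete) {
      idx <- match(x[, k], mk$empirical$support)
      if (anyNA(idx)) stop("value outside the fitted discrete support")
      marg <- marg + log(mk$empirical$pmf[idx])
    } else {
      if (is.null(mk$flow))
        stop("continuous margin has no density model; refit with margin_method = 'flow'")
      marg <- marg + flow_log_density(mk$flow, x[, k])
    }
  }
  R <- if (any(vine$discrete)) vine$fit_cfg$jitter_replicates else 1L
  cop <- matrix(0, n, R)
  for (r in seq_len(R)) {
    u <- .vine_pseudo_obs(vine, x, seed = .child_seed(seed, paste0("rep", r)))
    cop[, r] <- .vine_copula_log_density_u(vine, u)
  }
  # average replicate densities on the natural scale (log-sum-exp)
  mx <- apply(cop, 1, max)
  marg + mx + log(rowMeans(exp(cop - mx)))
}

#' Sample from a fitted C-vine
#'
#' Inverse-Rosenblatt sampling: independent uniforms are transformed to
#' copula-space coordinates through inverse h-functions (numeric inversion of
#' the fitted flow h-functions), then through the margin quantile transforms.
#' Discrete margins use the empirical quantile table, so sampled counts always
#' lie in the observed support.
#'
#' @param vine A fitted `cvine`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param return_copula_space If `TRUE`, also return the copula-space matrix.
#' @return A matrix of raw-scale samples (or a list when
#'   `return_copula_space`).
#' @export
vine_sample <- function(vine, n, seed = 1L, return_copula_space = FALSE) {
  d <- vine$d
  w <- .with_seed(.child_seed(seed, "uniforms"),
                  matrix(.clamp01(runif(n * d)), n, d))
  u_ord <- .cvine_rosenblatt_inverse(
    w,
    hinv = function(j, i, p, v) vine_hinv(vine$pair_copulas[[j]][[i]], p, v),
    hfun = function(j, i, uu, v) vine_hfunc(vine$pair_copulas[[j]][[i]], uu, v),
    d = d)
  u <- matrix(0, n, d)
  u[, vine$ordering] <- u_ord
  x <- matrix(0, n, d)
  for (k in seq_len(d)) {
    mk <- vine$margins[[k]]
    x[, k] <- if (!mk$discrete && !is.null(mk$flow)) {
      as.numeric(.flow_inverse(mk$flow, matrix(.clamp01(u[, k]), ncol = 1))) *
        mk$flow$data_scaling$scale + mk$flow$data_scaling$shift
    } else {
      margin_quantile(mk$empirical, u[, k])
    }
  }
  colnames(x) <- vine$var_names
  if (return_copula_space) list(x = x, u = u) else x
}

# Shared inverse-Rosenblatt recursion for a C-vine (Aas et al. style):
# hinv(j, i, p, v) and hfun(j, i, u, v) address the copula at tree j pairing
# the tree root with the (i+j)-th ordered variable (i is the within-tree pair
# index, 1-based).
.cvine_rosenblatt_inverse <- function(w, hinv, hfun, d) {
  n <- nrow(w)
  u <- matrix(0, n, d)
  v <- vector("list", d)
  for (i in seq_len(d)) v[[i]] <- vector("list", d)
  u[, 1] <- w[, 1]
  v[[1]][[1]] <- w[, 1]
  for (i in 2:d) {
    tt <- w[, i]
    for (k in (i - 1):1) {
      tt <- hinv(k, i - k, tt, v[[k]][[k]])
    }
    u[, i] <- tt
    v[[i]][[1]] <- tt
    if (i < d) {
      for (j in 1:(i - 1)) {
        v[[i]][[j + 1]] <- hfun(j, i - j, v[[i]][[j]], v[[j]][[j]])
      }
    }
  }
  u
}

# --- serialization -----------------------------------------------------------

#' Save / load a fitted C-vine
#'
#' The vine is stored as a directory tree mirroring the triangular pair-copula
#' array (`tree_j/pair_i/` flow directories), margin files, and `vine.json`
#' with the ordering, column types and diagnostics.
#'
#' @param vine A fitted `cvine`.
#' @param path Directory to create.
#' @return `save_cvine` returns `path` invisibly; `load_cvine` returns a
#'   `cvine`.
#' @export
save_cvine <- function(vine, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(ordering = vine$ordering, discrete = vine$discrete,
               d = vine$d, n = vine$n, var_names = vine$var_names,
               seed = vine$seed,
               jitter_replicates = vine$fit_cfg$jitter_replicates,
               fit_diagnostics = vine$fit_diagnostics)
  jsonlite::write_json(meta, file.path(path, "vine.json"), auto_unbox = TRUE,
                       digits = NA)
  for (k in seq_len(vine$d)) {
    mk <- vine$margins[[k]]
    mdir <- file.path(path, sprintf("margin_%d", k))
    dir.create(mdir, showWarnings = FALSE)
    if (mk$discrete) {
      write.csv(data.frame(support = mk$empirical$support,
                           pmf = mk$empirical$pmf),
                file.path(mdir, "table.csv"), row.names = FALSE)
    } else {
      writeLines(sprintf("%.17g", mk$empirical$sorted),
                 file.path(mdir, "sorted.txt"))
    }
    if (!is.null(mk$flow)) save_flow(mk$flow, file.path(mdir, "flow"))
  }
  for (j in seq_along(vine$pair_copulas)) {
    for (i in seq_along(vine$pair_copulas[[j]])) {
      save_flow(vine$pair_copulas[[j]][[i]],
                file.path(path, sprintf("tree_%d", j), sprintf("pair_%d", i)))
    }
  }
  invisible(path)
}

#' @rdname save_cvine
#' @export
load_cvine <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "vine.json"))
  d <- meta$d
  margins <- vector("list", d)
  for (k in seq_len(d)) {
    mdir <- file.path(path, sprintf("margin_%d", k))
    if (meta$discrete[k]) {
      tab <- read.csv(file.path(mdir, "table.csv"))
      cdf <- cumsum(tab$pmf); cdf[length(cdf)] <- 1
      emp <- structure(list(support = as.integer(tab$support), pmf = tab$pmf,
                            cdf = cdf, cdf_minus = c(0, head(cdf, -1)),
                            n = meta$n), class = "margin_table")
    } else {
      emp <- structure(list(sorted = as.numeric(
        readLines(file.path(mdir, "sorted.txt"))), n = meta$n),
        class = "margin_ecdf")
    }
    fl <- if (dir.exists(file.path(mdir, "flow")))
      load_flow(file.path(mdir, "flow")) else NULL
    margins[[k]] <- list(empirical = emp, flow = fl,
                         discrete = meta$discrete[k])
  }
  pair_copulas <- vector("list", d - 1)
  for (j in seq_len(d - 1)) {
    pair_copulas[[j]] <- lapply(seq_len(d - j), function(i)
      load_flow(file.path(path, sprintf("tree_%d", j), sprintf("pair_%d", i))))
  }
  structure(list(ordering = meta$ordering, margins = margins,
                 discrete = meta$discrete, pair_copulas = pair_copulas,
                 fit_diagnostics = as.data.frame(meta$fit_diagnostics),
                 d = d, n = meta$n, var_names = meta$var_names,
                 seed = meta$seed,
                 fit_cfg = utils::modifyList(
                   cvine_fit_config(),
                   list(jitter_replicates = meta$jitter_replicates))),
            class = "cvine")
}
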