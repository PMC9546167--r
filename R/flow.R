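# Rational-quadratic spline normalizing flows with a uniform base.
#
# A flow maps observations (in [0,1]^dim) to the uniform base distribution
# through a stack of monotone spline layers; the log-density of a point is the
# accumulated log|det| of that normalizing direction and sampling pushes
# uniform draws through the inverse stack. One-dimensional flows stack
# unconditional splines. Two-dimensional flows stack coupling blocks: an
# unconditional spline acts on one coordinate and a conditioner network (one
# tanh hidden layer) reads that same coordinate to emit the spline parameters
# applied to the other coordinate; the roles swap between consecutive blocks,
# so the inverse remains a single pass.

#' Build an (untrained) spline flow
#'
#' @param hyper A list with `n_layers` (spline layers or coupling blocks),
#'   `hidden_units` (conditioner width, 2D only), `n_bins` (spline knots) and
#'   `dim` (1 or 2).
#' @param seed Integer seed controlling parameter initialization.
#' @return An object of class `flow`, initialized near the identity map so the
#'   initial density is approximately uniform.
#' @export
build_flow <- function(hyper, seed = 1L) {
  stopifnot(hyper$dim %in% c(1, 2), hyper$n_layers >= 1, hyper$n_bins >= 2)
  K <- as.integer(hyper$n_bins)
  Hd <- as.integer(if (is.null(hyper$hidden_units)) 16L else hyper$hidden_units)
  hyper$hidden_units <- Hd
  layers <- .with_seed(seed, lapply(seq_len(hyper$n_layers), function(l) {
    par <- list(a = rep(0, K), h = rep(0, K),
                b = rep(.deriv_raw_identity(), K - 1))
    if (hyper$dim == 2) {
      n_out <- 3L * K - 1L
      par$W1 <- matrix(rnorm(Hd, sd = sqrt(2)), 1, Hd)
      par$b1 <- rep(0, Hd)
      par$W2 <- matrix(rnorm(Hd * n_out, sd = 0.01 * sqrt(2 / Hd)), Hd, n_out)
      par$b2 <- rep(0, n_out)
      list(kind = "coupling", cond_on = if (l %% 2 == 1) 1L else 2L, par = par)
    } else {
      list(kind = "spline", par = par)
    }
  }))
  structure(list(hyper = hyper, layers = layers,
                 data_scaling = list(shift = 0, scale = 1),
                 trained = FALSE, train_log = NULL, seed = as.integer(seed)),
            class = "flow")
}

#' @export
print.flow <- function(x, ...) {
  cat(sprintf("<flow> dim=%d layers=%d bins=%d hidden=%d %s\n",
              x$hyper$dim, x$hyper$n_layers, x$hyper$n_bins,
              x$hyper$hidden_units,
              if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

# --- forward (normalizing) pass with optional cache for backprop ------------

# conditioner network + constraints, fused in C++ (hot path)
.cond_params <- function(A, par, K, want_cache = FALSE) {
  cpp_conditioner_forward(A, par$W1, par$b1, par$W2, par$b2, K,
                          MIN_BIN, MIN_DERIV, .deriv_raw_identity(),
                          want_cache)
}

.shared_params <- function(par) {
  cw <- .constrain_bins(matrix(par$a, 1))
  ch <- .constrain_bins(matrix(par$h, 1))
  cd <- .constrain_derivs(matrix(par$b, 1))
  list(W = cw$value, H = ch$value, D = cd$value, cw = cw, ch = ch, cd = cd)
}

.flow_forward <- function(flow, x, want_cache = FALSE) {
  n <- nrow(x)
  logdet <- numeric(n)
  caches <- if (want_cache) vector("list", length(flow$layers)) else NULL
  u <- x
  for (l in seq_along(flow$layers)) {
    layer <- flow$layers[[l]]
    if (layer$kind == "spline") {
      sp <- .shared_params(layer$par)
      r <- cpp_rqs_forward(u[, 1], sp$W, sp$H, sp$D)
      if (want_cache) caches[[l]] <- list(x = u[, 1], sp = sp, bin = r$bin)
      u[, 1] <- r$y
      logdet <- logdet + r$logdet
    } else {
      ca <- layer$cond_on; cb <- 3L - ca
      A <- u[, ca]; B <- u[, cb]
      spA <- .shared_params(layer$par)
      rA <- cpp_rqs_forward(A, spA$W, spA$H, spA$D)
      cp <- .cond_params(A, layer$par, flow$hyper$n_bins, want_cache)
      rB <- cpp_rqs_forward(B, cp$W, cp$H, cp$D)
      if (want_cache)
        caches[[l]] <- list(A = A, B = B, spA = spA, binA = rA$bin,
                            cp = cp, binB = rB$bin)
      u[, ca] <- rA$y
      u[, cb] <- rB$y
      logdet <- logdet + rA$logdet + rB$logdet
    }
  }
  list(u = u, logdet = logdet, caches = caches)
}

# gradient of loss = -mean(logdet) with respect to all layer parameters
.flow_backward <- function(flow, caches, n) {
  gld <- rep(-1 / n, n)          # dL/d(logdet contribution of each layer)
  grads <- vector("list", length(flow$layers))
  gU <- matrix(0, n, flow$hyper$dim)  # gradient wrt the layer output
  K <- flow$hyper$n_bins
  for (l in rev(seq_along(flow$layers))) {
    layer <- flow$layers[[l]]
    cc <- caches[[l]]
    if (layer$kind == "spline") {
      bw <- cpp_rqs_backward(cc$x, cc$sp$W, cc$sp$H, cc$sp$D, cc$bin,
                             gU[, 1], gld)
      ga <- .constrain_bins_bwd(cc$sp$cw, matrix(colSums(bw$gW), 1))
      gh <- .constrain_bins_bwd(cc$sp$ch, matrix(colSums(bw$gH), 1))
      gb <- .constrain_derivs_bwd(cc$sp$cd, matrix(colSums(bw$gD), 1))
      grads[[l]] <- list(a = as.numeric(ga), h = as.numeric(gh),
                         b = as.numeric(gb))
      gU[, 1] <- bw$gx
    } else {
      ca <- layer$cond_on; cb <- 3L - ca
      # conditioned spline on B
      bwB <- cpp_rqs_backward(cc$B, cc$cp$W, cc$cp$H, cc$cp$D, cc$binB,
                              gU[, cb], gld)
      cb_bw <- cpp_conditioner_backward(cc$A, layer$par$W1, layer$par$W2,
                                        cc$cp$Hh, cc$cp$smW, cc$cp$smH,
                                        cc$cp$sig, bwB$gW, bwB$gH, bwB$gD,
                                        MIN_BIN)
      gW1 <- cb_bw$gW1; gb1 <- cb_bw$gb1
      gW2 <- cb_bw$gW2; gb2 <- cb_bw$gb2
      gA_mlp <- cb_bw$ga
      # unconditional spline on A
      bwA <- cpp_rqs_backward(cc$A, cc$spA$W, cc$spA$H, cc$spA$D, cc$binA,
                              gU[, ca], gld)
      ga <- .constrain_bins_bwd(cc$spA$cw, matrix(colSums(bwA$gW), 1))
      gh <- .constrain_bins_bwd(cc$spA$ch, matrix(colSums(bwA$gH), 1))
      gb <- .constrain_derivs_bwd(cc$spA$cd, matrix(colSums(bwA$gD), 1))
      grads[[l]] <- list(a = as.numeric(ga), h = as.numeric(gh),
                         b = as.numeric(gb), W1 = gW1, b1 = gb1,
                         W2 = gW2, b2 = gb2)
      gU[, ca] <- bwA$gx + gA_mlp
      gU[, cb] <- bwB$gx
    }
  }
  grads
}

# inverse (generative) pass: base point -> data point in [0,1]^dim
.flow_inverse <- function(flow, u) {
  x <- u
  for (l in rev(seq_along(flow$layers))) {
    layer <- flow$layers[[l]]
    if (layer$kind == "spline") {
      sp <- .shared_params(layer$par)
      x[, 1] <- cpp_rqs_inverse(x[, 1], sp$W, sp$H, sp$D)$x
    } else {
      ca <- layer$cond_on; cb <- 3L - ca
      spA <- .shared_params(layer$par)
      A <- cpp_rqs_inverse(x[, ca], spA$W, spA$H, spA$D)$x
      cp <- .cond_params(A, layer$par, flow$hyper$n_bins)
      x[, cb] <- cpp_rqs_inverse(x[, cb], cp$W, cp$H, cp$D)$x
      x[, ca] <- A
    }
  }
  x
}

# --- training ---------------------------------------------------------------

#' Default flow training configuration
#'
#' @param batch_size Minibatch size for stochastic gradient training.
#' @param max_epochs Upper bound on training epochs.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience in epochs without validation
#'   improvement.
#' @param val_fraction Fraction of the data held out for validation.
#' @return A list of training settings.
#' @export
flow_train_config <- function(batch_size = 2048, max_epochs = 600, lr = 3e-3,
                              patience = 40, val_fraction = 0.1) {
  list(batch_size = batch_size, max_epochs = max_epochs, lr = lr,
       patience = patience, val_fraction = val_fraction)
}

.adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

.adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Fit a spline flow by maximum likelihood
#'
#' Trains the flow by stochastic gradient ascent (Adam) on the mean
#' log-likelihood under the change-of-variables formula, holding out a
#' validation fraction for early stopping and returning the parameters with
#' the best validation log-likelihood.
#'
#' @param flow A flow from [build_flow()].
#' @param data Numeric vector (dim 1) or matrix with values in `(0, 1)`; for
#'   one-dimensional margin flows on an arbitrary scale, use
#'   [fit_margin_flow()].
#' @param train_cfg A list from [flow_train_config()]; partial lists are
#'   merged with the defaults.
#' @param seed Integer seed for the data split and batch shuffling.
#' @return The trained flow with a `train_log` data frame (epoch, train and
#'   validation mean log-likelihood).
#' @export
fit_flow <- function(flow, data, train_cfg = list(), seed = 1L) {
  cfg <- utils::modifyList(flow_train_config(), train_cfg)
  x <- if (is.null(dim(data))) matrix(data, ncol = 1) else as.matrix(data)
  if (ncol(x) != flow$hyper$dim) stop("data dimension does not match flow")
  if (nrow(x) < 100) stop("need at least 100 training points")
  x <- .clamp01(x)
  n <- nrow(x)
  n_val <- max(1L, floor(cfg$val_fraction * n))
  idx <- .with_seed(.child_seed(seed, "split"), sample.int(n))
  val <- x[idx[seq_len(n_val)], , drop = FALSE]
  trn <- x[idx[-seq_len(n_val)], , drop = FALSE]
  n_trn <- nrow(trn)

  get_params <- function() lapply(flow$layers, `[[`, "par")
  set_params <- function(ps) {
    for (l in seq_along(ps)) flow$layers[[l]]$par <<- ps[[l]]
  }
  adam <- lapply(get_params(), .adam_init)
  t_step <- 0L
  val_ll <- function() mean(.flow_forward(flow, val)$logdet)

  best_val <- -Inf; best_params <- get_params(); best_epoch <- 0L
  log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
  rng_seed <- .child_seed(seed, "shuffle")
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- .with_seed(rng_seed + epoch, sample.int(n_trn))
    starts <- seq(1, n_trn, by = cfg$batch_size)
    ep_ll <- 0
    for (s in starts) {
      rows <- ord[s:min(s + cfg$batch_size - 1, n_trn)]
      xb <- trn[rows, , drop = FALSE]
      fw <- .flow_forward(flow, xb, want_cache = TRUE)
      loss <- -mean(fw$logdet)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      ep_ll <- ep_ll + sum(fw$logdet)
      grads <- .flow_backward(flow, fw$caches, length(rows))
      t_step <- t_step + 1L
      for (l in seq_along(flow$layers)) {
        for (nm in names(grads[[l]])) {
          upd <- .adam_step(flow$layers[[l]]$par[[nm]], grads[[l]][[nm]],
                            adam[[l]][[nm]], cfg$lr, t_step)
          flow$layers[[l]]$par[[nm]] <- upd$par
          adam[[l]][[nm]] <- upd$state
        }
      }
    }
    v <- val_ll()
    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, ep_ll / n_trn)
    log_val <- c(log_val, v)
    if (v > best_val) {
      best_val <- v
      best_params <- get_params()
      best_epoch <- epoch
    } else if (epoch - best_epoch >= cfg$patience) break
  }
  set_params(best_params)
  flow$trained <- TRUE
  flow$train_log <- data.frame(epoch = log_epoch, train_ll = log_train,
                               val_ll = log_val)
  flow$best_val_ll <- best_val
  flow$seed <- as.integer(seed)
  flow
}

#' Fit a one-dimensional margin flow on raw data
#'
#' Affinely rescales the data to the unit interval using the observed range
#' extended by `pad_sd` sample standard deviations on each side, then fits a
#' 1D spline flow. The affine Jacobian is included in [flow_log_density()] and
#' undone by [flow_sample()]. The padding trades tail coverage against
#' probability mass stranded outside the data range; one standard deviation
#' beyond the observed extremes keeps unseen points in-domain while leaving
#' the stranded mass negligible.
#'
#' @param data Numeric vector of raw observations.
#' @param hyper Flow hyperparameters (`dim` is forced to 1).
#' @param train_cfg,seed Passed to [fit_flow()].
#' @param pad_sd Padding beyond the observed range, in sample standard
#'   deviations.
#' @return A trained flow with a `data_scaling` attribute.
#' @export
fit_margin_flow <- function(data, hyper = list(n_layers = 2, n_bins = 8),
                            train_cfg = list(), seed = 1L, pad_sd = 1) {
  hyper$dim <- 1L
  s <- sd(data)
  lo <- min(data) - pad_sd * s
  hi <- max(data) + pad_sd * s
  flow <- build_flow(hyper, seed = .child_seed(seed, "init"))
  flow$data_scaling <- list(shift = lo, scale = hi - lo)
  z <- (data - lo) / (hi - lo)
  fit_flow(flow, z, train_cfg = train_cfg, seed = seed)
}

#' Log-density under a flow
#'
#' Computes `log p(x)` via the change-of-variables formula: the accumulated
#' log-Jacobian of the normalizing direction (the uniform base contributes
#' zero) plus, for margin flows, the affine data-scaling Jacobian.
#'
#' @param flow A flow.
#' @param points Numeric vector (dim 1) or matrix of evaluation points.
#' @return Numeric vector of log densities.
#' @export
flow_log_density <- function(flow, points) {
  x <- if (is.null(dim(points))) matrix(points, ncol = 1) else as.matrix(points)
  if (ncol(x) != flow$hyper$dim) stop("point dimension does not match flow")
  sc <- flow$data_scaling
  z <- (x - sc$shift) / sc$scale
  if (any(z < -1e-9 | z > 1 + 1e-9))
    stop("point outside the flow's domain after scaling")
  fw <- .flow_forward(flow, .clamp01(z))
  fw$logdet - flow$hyper$dim * log(sc$scale)
}

#' Sample from a flow
#'
#' Draws uniform base points and pushes them through the inverse transform
#' (inverse sampling); margin flows are mapped back to the raw data scale.
#'
#' @param flow A flow.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A numeric matrix with `n` rows (`dim` columns).
#' @export
flow_sample <- function(flow, n, seed = 1L) {
  u <- .with_seed(seed, matrix(runif(n * flow$hyper$dim), n))
  x <- .flow_inverse(flow, .clamp01(u))
  sc <- flow$data_scaling
  x * sc$scale + sc$shift
}

#' Random hyperparameter search for a flow
#'
#' Samples hyperparameter configurations uniformly from the search space, fits
#' each one, and returns the fit with the highest validation log-likelihood
#' (ties broken by fewer parameters).
#'
#' @param data Training data in `(0, 1)^dim`.
#' @param dim Flow dimension (1 or 2).
#' @param search_space A list with candidate vectors `n_layers`,
#'   `hidden_units` and `n_bins`.
#' @param n_trials Number of sampled configurations.
#' @param val_fraction Validation fraction used for model selection.
#' @param seed Integer seed.
#' @param train_cfg Training configuration overrides.
#' @return The best trained flow; the trial table is attached as attribute
#'   `search_log`.
#' @export
flow_random_search <- function(data, dim,
                               search_space = list(n_layers = c(1, 2, 3),
                                                   hidden_units = c(16, 32, 64, 128),
                                                   n_bins = c(4, 8, 16, 32)),
                               n_trials = 10, val_fraction = 0.1, seed = 1L,
                               train_cfg = list()) {
  stopifnot(n_trials >= 1)
  train_cfg$val_fraction <- val_fraction
  draws <- .with_seed(.child_seed(seed, "hyper"), data.frame(
    n_layers = sample(search_space$n_layers, n_trials, replace = TRUE),
    hidden_units = sample(search_space$hidden_units, n_trials, replace = TRUE),
    n_bins = sample(search_space$n_bins, n_trials, replace = TRUE)))
  best <- NULL; best_val <- -Inf; best_np <- Inf
  vals <- numeric(n_trials); fails <- character(n_trials)
  for (t in seq_len(n_trials)) {
    hy <- list(n_layers = draws$n_layers[t], hidden_units = draws$hidden_units[t],
               n_bins = draws$n_bins[t], dim = dim)
    ft <- tryCatch(
      fit_flow(build_flow(hy, seed = .child_seed(seed, paste0("trial", t))),
               data, train_cfg = train_cfg,
               seed = .child_seed(seed, paste0("fit", t))),
      error = function(e) e)
    if (inherits(ft, "error")) {
      vals[t] <- NA; fails[t] <- conditionMessage(ft)
      next
    }
    np <- .flow_n_params(ft)
    vals[t] <- ft$best_val_ll
    if (ft$best_val_ll > best_val ||
        (ft$best_val_ll == best_val && np < best_np)) {
      best <- ft; best_val <- ft$best_val_ll; best_np <- np
    }
  }
  if (is.null(best)) stop("random search failed: all trials diverged")
  draws$val_ll <- vals
  attr(best, "search_log") <- draws
  best
}

.flow_n_params <- function(flow) {
  sum(vapply(flow$layers, function(l) sum(lengths(lapply(l$par, as.numeric))),
             numeric(1)))
}

# --- text serialization (bit-exact reload) ----------------------------------

#' Save / load a flow model
#'
#' A flow is stored as a directory holding `meta.json` (hyperparameters, data
#' scaling, seed, training summary) and `params.txt` (one named parameter per
#' line, printed with 17 significant digits so the reload is bit-exact).
#'
#' @param flow A flow.
#' @param path Directory to create.
#' @return `save_flow` returns `path` invisibly; `load_flow` returns a flow.
#' @export
save_flow <- function(flow, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(hyper = flow$hyper, data_scaling = flow$data_scaling,
               trained = flow$trained, seed = flow$seed,
               best_val_ll = flow$best_val_ll,
               cond_on = vapply(flow$layers, function(l)
                 if (is.null(l$cond_on)) NA_integer_ else l$cond_on, integer(1)))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  lines <- sprintf("scaling.%s %s", c("shift", "scale"),
                   sprintf("%.17g", c(flow$data_scaling$shift,
                                      flow$data_scaling$scale)))
  for (l in seq_along(flow$layers)) {
    for (nm in names(flow$layers[[l]]$par)) {
      v <- flow$layers[[l]]$par[[nm]]
      lines <- c(lines, sprintf("L%d.%s %s", l, nm,
                                paste(sprintf("%.17g", as.numeric(v)),
                                      collapse = " ")))
    }
  }
  writeLines(lines, file.path(path, "params.txt"))
  invisible(path)
}

#' @rdname save_flow
#' @export
load_flow <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  flow <- build_flow(as.list(meta$hyper), seed = meta$seed)
  flow$data_scaling <- as.list(meta$data_scaling)
  flow$trained <- meta$trained
  flow$best_val_ll <- meta$best_val_ll
  lines <- readLines(file.path(path, "params.txt"))
  for (ln in lines) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    key <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
    vals <- as.numeric(parts[-1])
    if (key[1] == "scaling") {
      flow$data_scaling[[key[2]]] <- vals
      next
    }
    l <- as.integer(sub("L", "", key[1])); nm <- key[2]
    old <- flow$layers[[l]]$par[[nm]]
    flow$layers[[l]]$par[[nm]] <- if (is.matrix(old))
      matrix(vals, nrow(old), ncol(old)) else vals
  }
  flow
}
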