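test_that("untrained flows start at the uniform density", {
  for (dim in 1:2) {
    fl <- build_flow(list(n_layers = 2, hidden_units = 16, n_bins = 8,
                          dim = dim), seed = 41)
    pts <- matrix(runif(200 * dim), ncol = dim)
    expect_lt(max(abs(flow_log_density(fl, pts))), 0.1)
  }
  # untrained 2D draws are nearly independent
  fl2 <- build_flow(list(n_layers = 2, hidden_units = 16, n_bins = 8, dim = 2),
                    seed = 42)
  d <- flow_sample(fl2, 8000, seed = 43)
  expect_lt(abs(kendall_tau_empirical(d[, 1], d[, 2])), 0.03)
  # untrained 1D samples are uniform
  f1 <- build_flow(list(n_layers = 2, n_bins = 8, dim = 1), seed = 44)
  s1 <- flow_sample(f1, 5000, seed = 45)
  expect_gt(suppressWarnings(ks.test(as.numeric(s1), "punif"))$p.value, 0.01)
})

test_that("initialization and sampling are seed-reproducible", {
  a <- build_flow(list(n_layers = 2, hidden_units = 8, n_bins = 6, dim = 2),
                  seed = 7)
  b <- build_flow(list(n_layers = 2, hidden_units = 8, n_bins = 6, dim = 2),
                  seed = 7)
  expect_identical(a$layers, b$layers)
  expect_identical(flow_sample(a, 50, seed = 3), flow_sample(b, 50, seed = 3))
})

test_that("flow gradients match finite differences", {
  fw <- flowvine:::.flow_forward
  bw <- flowvine:::.flow_backward
  set.seed(46)
  flow <- build_flow(list(n_layers = 2, hidden_units = 6, n_bins = 4, dim = 2),
                     seed = 47)
  for (l in 1:2) {
    flow$layers[[l]]$par$a <- rnorm(4, sd = 0.4)
    flow$layers[[l]]$par$h <- rnorm(4, sd = 0.4)
    flow$layers[[l]]$par$b <- rnorm(3, sd = 0.4) + flowvine:::.deriv_raw_identity()
    flow$layers[[l]]$par$W2 <- matrix(rnorm(6 * 11, sd = 0.3), 6, 11)
    flow$layers[[l]]$par$b2 <- rnorm(11, sd = 0.2)
  }
  x <- matrix(runif(30), 15, 2)
  loss <- function(fl) -mean(fw(fl, x)$logdet)
  g <- bw(flow, fw(flow, x, want_cache = TRUE)$caches, 15)
  for (l in 1:2) for (nm in names(g[[l]])) {
    p0 <- flow$layers[[l]]$par[[nm]]
    idx <- seq_len(min(5, length(p0)))
    for (ii in idx) {
      f1 <- flow; f1$layers[[l]]$par[[nm]][ii] <- p0[ii] + 1e-6
      f2 <- flow; f2$layers[[l]]$par[[nm]][ii] <- p0[ii] - 1e-6
      fd <- (loss(f1) - loss(f2)) / 2e-6
      expect_equal(as.numeric(g[[l]][[nm]])[ii], fd, tolerance = 1e-5)
    }
  }
})

test_that("fitting independence data yields a flat density on held-out draws", {
  set.seed(48)
  dat <- matrix(runif(10000), 5000, 2)
  fl <- fit_flow(build_flow(list(n_layers = 2, hidden_units = 16, n_bins = 8,
                                 dim = 2), seed = 49),
                 dat, train_cfg = list(max_epochs = 80, patience = 15),
                 seed = 50)
  held <- matrix(runif(4000), 2000, 2)
  mean_log2 <- mean(flow_log_density(fl, held)) / log(2)
  expect_lt(abs(mean_log2), 0.05)
  # early-stopping contract: returned validation score never below epoch 1
  expect_gte(fl$best_val_ll, fl$train_log$val_ll[1])
})

test_that("trained flows remain invertible and normalized", {
  cf <- cached_pair_fit("gaussian", "strong")
  x <- matrix(runif(2e4), 1e4, 2)
  u <- flowvine:::.flow_forward(cf$flow, x)$u
  back <- flowvine:::.flow_inverse(cf$flow, u)
  expect_lt(max(abs(back - x)), 1e-6)
  g <- seq(1 / 400, 1 - 1 / 400, length.out = 200)
  pts <- as.matrix(expand.grid(g, g))
  integ <- mean(exp(flow_log_density(cf$flow, pts)))
  expect_gt(integ, 0.98); expect_lt(integ, 1.02)
})

test_that("margin flows recover a bimodal density and its samples", {
  set.seed(51)
  x <- c(rnorm(2500, -2, 0.7), rnorm(2500, 2, 0.7))
  fl <- fit_margin_flow(x, seed = 52)
  s <- as.numeric(flow_sample(fl, 4000, seed = 53))
  expect_lt(abs(mean(s) - mean(x)), 0.15)
  expect_lt(abs(sd(s) - sd(x)), 0.2)
  # two modes: density at the modes well above density at the trough
  ld <- flow_log_density(fl, c(-2, 0, 2))
  expect_gt(min(ld[c(1, 3)]) - ld[2], 1)
  # quadrature of the raw-scale density integrates to 1
  grid <- seq(min(x) - 1, max(x) + 1, length.out = 2000)
  integ <- sum(exp(flow_log_density(fl, grid))) * diff(grid[1:2])
  expect_gt(integ, 0.97); expect_lt(integ, 1.03)
})

test_that("training reports divergence with the epoch", {
  set.seed(54)
  dat <- matrix(runif(400), 200, 2)
  fl <- build_flow(list(n_layers = 2, hidden_units = 8, n_bins = 4, dim = 2),
                   seed = 1)
  fl$layers[[1]]$par$W2[1, 1] <- NaN  # corrupt state -> non-finite loss
  expect_error(fit_flow(fl, dat, train_cfg = list(max_epochs = 5), seed = 2),
               "diverged.*epoch 1")
})

test_that("random search returns the best-validation trial", {
  set.seed(55)
  uv <- copula_sample(copula_spec("gaussian", rho = 0.8), 1500, seed = 56)
  tc <- list(max_epochs = 40, patience = 10)
  single <- flow_random_search(uv, dim = 2, n_trials = 1, seed = 57,
                               train_cfg = tc)
  expect_s3_class(single, "flow")
  expect_equal(nrow(attr(single, "search_log")), 1)
  multi <- flow_random_search(uv, dim = 2,
                              search_space = list(n_layers = 1:2,
                                                  hidden_units = c(8, 16),
                                                  n_bins = c(4, 8)),
                              n_trials = 4, seed = 57, train_cfg = tc)
  log <- attr(multi, "search_log")
  expect_equal(nrow(log), 4)
  expect_equal(multi$best_val_ll, max(log$val_ll, na.rm = TRUE))
})

test_that("flows serialize to text and reload bit-exactly", {
  cf <- cached_pair_fit("gaussian", "strong")
  dir <- tempfile("flow_")
  save_flow(cf$flow, dir)
  re <- load_flow(dir)
  pts <- matrix(runif(500), 250, 2)
  expect_identical(flow_log_density(re, pts), flow_log_density(cf$flow, pts))
  expect_identical(flow_sample(re, 100, seed = 9),
                   flow_sample(cf$flow, 100, seed = 9))
  unlink(dir, recursive = TRUE)
})
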