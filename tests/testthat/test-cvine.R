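# Small problem sizes keep the vine unit tests quick; the scaled simulation
# study runs in test-acceptance.R.
.quick_cfg <- list(margin_method = "empirical",
                   hyper = list(n_layers = 2, hidden_units = 16, n_bins = 8),
                   train = list(max_epochs = 60, patience = 15))

test_that("variables are ordered by total absolute Kendall tau", {
  set.seed(61)
  n <- 600
  z <- rnorm(n)
  # V2 is the hub: correlated with both others; V3 only weakly attached
  x <- cbind(z + rnorm(n, sd = 1.2),
             z,
             0.3 * z + rnorm(n, sd = 1.5))
  u <- apply(x, 2, function(c) rank(c) / (n + 1))
  tau <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3)
    tau[i, j] <- tau[j, i] <- abs(kendall_tau_empirical(u[, i], u[, j]))
  expect_equal(order_variables(u), order(-rowSums(tau), 1:3))
  expect_equal(order_variables(u)[1], 2L)
  # d = 2 with exchangeable columns: deterministic tie-break by index
  uu <- cbind(u[, 1], u[, 1])
  expect_equal(order_variables(uu), c(1L, 2L))
})

test_that("the fitted vine has the triangular pair-copula structure", {
  case <- benchmark_case(4, "gaussian", "strong", "continuous")
  x <- generate_dataset(build_ground_truth_vine(case), 800, seed = 62)
  vine <- fit_cvine(x, column_types = rep("continuous", 4),
                    fit_cfg = .quick_cfg, seed = 63)
  expect_equal(lengths(vine$pair_copulas), c(3L, 2L, 1L))
  expect_equal(nrow(vine$fit_diagnostics), 6)
  expect_equal(sort(vine$ordering), 1:4)
})

test_that("flow h-functions agree with closed-form oracles", {
  # near-identity flow: h(u | v) is close to u
  fl0 <- build_flow(list(n_layers = 2, hidden_units = 16, n_bins = 8, dim = 2),
                    seed = 64)
  u <- seq(0.1, 0.9, by = 0.2)
  expect_lt(max(abs(vine_hfunc(fl0, u, rep(0.5, 5)) - u)), 0.02)
  expect_equal(vine_hfunc(fl0, rep(1, 3), c(0.2, 0.5, 0.8)), rep(1, 3))
  # flow fitted to Clayton theta = 2: h(0.5 | 0.5) near the closed form
  cf <- cached_pair_fit("clayton", "weak")
  h_true <- copula_hfunc(cf$spec, 0.5, 0.5)
  expect_lt(abs(vine_hfunc(cf$flow, 0.5, 0.5) - h_true), 0.05)
  # inverse h-function round-trips through the same grid
  p <- seq(0.05, 0.95, by = 0.1)
  v <- rep(0.4, length(p))
  expect_equal(vine_hfunc(cf$flow, vine_hinv(cf$flow, p, v), v), p,
               tolerance = 1e-3)
})

test_that("a 2D vine density equals margins plus the pair copula density", {
  set.seed(65)
  case <- benchmark_case(2, "gaussian", "strong", "continuous")
  x <- generate_dataset(build_ground_truth_vine(case), 1200, seed = 66)
  vine <- fit_cvine(x, column_types = rep("continuous", 2),
                    fit_cfg = utils::modifyList(.quick_cfg,
                                                list(margin_method = "flow")),
                    seed = 67)
  xs <- x[1:80, ]
  direct <- flow_log_density(vine$margins[[1]]$flow, xs[, 1]) +
    flow_log_density(vine$margins[[2]]$flow, xs[, 2]) +
    flowvine:::.vine_copula_log_density_u(vine,
      flowvine:::.vine_pseudo_obs(vine, xs, seed = flowvine:::.child_seed(1, "rep1")))
  expect_equal(vine_log_density(vine, xs, seed = 1), direct, tolerance = 1e-10)
  # both orderings model the same joint: mean held-out log-densities agree
  vine_b <- fit_cvine(x, column_types = rep("continuous", 2),
                      fit_cfg = utils::modifyList(.quick_cfg,
                        list(margin_method = "flow", ordering = c(2, 1))),
                      seed = 67)
  held <- generate_dataset(build_ground_truth_vine(case), 400, seed = 68)
  expect_lt(abs(mean(vine_log_density(vine, held, seed = 2)) -
                mean(vine_log_density(vine_b, held, seed = 2))), 0.1)
})

test_that("held-out vine log-density approaches the true differential entropy", {
  case <- benchmark_case(2, "gaussian", "strong", "continuous")
  gt <- build_ground_truth_vine(case)
  x <- generate_dataset(gt, 4000, seed = 69)
  vine <- fit_cvine(x, column_types = rep("continuous", 2),
                    fit_cfg = list(margin_method = "flow"), seed = 70)
  held <- generate_dataset(gt, 3000, seed = 71)
  nll <- -mean(vine_log_density(vine, held, seed = 3))
  # Monte-Carlo oracle: h(X) = 2 h(N(0,1)) + copula entropy (in nats)
  h_true <- 2 * (0.5 * log(2 * pi * exp(1))) +
    copula_entropy_mc(gt$spec, 20000, seed = 72)$value * log(2)
  expect_lt(abs(nll - h_true), 0.1)
})

test_that("vine samples reproduce dependence and respect discrete supports", {
  case <- benchmark_case(3, "clayton", "strong", "continuous")
  gt <- build_ground_truth_vine(case)
  x <- generate_dataset(gt, 3000, seed = 73)
  vine <- fit_cvine(x, column_types = rep("continuous", 3),
                    fit_cfg = utils::modifyList(.quick_cfg,
                      list(ordering = 1:3,
                           train = list(max_epochs = 120, patience = 20))),
                    seed = 74)
  s <- vine_sample(vine, 4000, seed = 75, return_copula_space = TRUE)
  # tree-1 dependence recovered on the raw scale
  expect_lt(abs(kendall_tau_empirical(s$x[, 1], s$x[, 2]) - 5 / 7), 0.05)
  # copula-space coordinates are uniform
  for (k in 1:3) {
    ks <- suppressWarnings(ks.test(s$u[, k], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
  # discrete margins stay on the observed support
  case_d <- benchmark_case(2, "gaussian", "strong", "discrete")
  xd <- generate_dataset(build_ground_truth_vine(case_d), 1500, seed = 76)
  vd <- fit_cvine(xd, column_types = rep("discrete", 2),
                  fit_cfg = .quick_cfg, seed = 77)
  sd_ <- vine_sample(vd, 2000, seed = 78)
  expect_true(all(sd_[, 1] %in% unique(xd[, 1])))
  expect_true(all(sd_[, 2] %in% unique(xd[, 2])))
})

test_that("vines serialize to a directory tree and reload exactly", {
  case <- benchmark_case(3, "gaussian", "weak", "continuous")
  x <- generate_dataset(build_ground_truth_vine(case), 600, seed = 79)
  vine <- fit_cvine(x, column_types = rep("continuous", 3),
                    fit_cfg = utils::modifyList(.quick_cfg,
                                                list(margin_method = "flow",
                                                     train = list(max_epochs = 30,
                                                                  patience = 10))),
                    seed = 80)
  dir <- tempfile("vine_")
  save_cvine(vine, dir)
  re <- load_cvine(dir)
  expect_identical(re$ordering, vine$ordering)
  expect_identical(vine_sample(re, 50, seed = 81), vine_sample(vine, 50, seed = 81))
  expect_equal(vine_log_density(re, x[1:20, ], seed = 82),
               vine_log_density(vine, x[1:20, ], seed = 82), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("independent columns produce near-zero pair copula entropies", {
  set.seed(83)
  x <- matrix(runif(4 * 1200), ncol = 4)
  vine <- fit_cvine(x, column_types = rep("continuous", 4),
                    fit_cfg = .quick_cfg, seed = 84)
  for (j in 1:3) for (i in seq_along(vine$pair_copulas[[j]])) {
    ent <- copula_entropy_mc(vine$pair_copulas[[j]][[i]], K = 2000, seed = 85)
    expect_lt(abs(ent$value), 0.1)
  }
})
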