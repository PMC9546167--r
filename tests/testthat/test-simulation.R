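test_that("ground-truth vines resolve the study parameters", {
  c1 <- benchmark_case(4, "clayton", "weak", "continuous")
  expect_equal(c1$param, 2)
  expect_equal(benchmark_case(4, "clayton", "strong")$param, 5)
  expect_equal(benchmark_case(4, "frank", "weak")$param, 3)
  expect_equal(benchmark_case(4, "frank", "strong")$param, 7)
  expect_equal(benchmark_case(4, "gaussian", "weak")$param, 0.4)
  expect_equal(benchmark_case(8, "gaussian", "strong")$param, 0.8)
  gt <- build_ground_truth_vine(c1)
  expect_equal(gt$d * (gt$d - 1) / 2, 6)
  expect_equal(build_ground_truth_vine(benchmark_case(8, "frank", "weak"))$d *
                 7 / 2, 28)
  expect_equal(build_ground_truth_vine(
    benchmark_case(4, "gaussian", "strong"))$spec$rho, 0.8)
})

test_that("dataset generation reproduces the prescribed dependence", {
  gt <- build_ground_truth_vine(benchmark_case(4, "clayton", "strong",
                                               "continuous"))
  x <- generate_dataset(gt, 5000, seed = 111)
  for (j in 2:4)
    expect_lt(abs(kendall_tau_empirical(x[, 1], x[, j]) - 5 / 7), 0.03)
  expect_identical(generate_dataset(gt, 200, seed = 5),
                   generate_dataset(gt, 200, seed = 5))
  ind <- build_ground_truth_vine(benchmark_case(4, "independence", "weak",
                                                "continuous"))
  xi <- generate_dataset(ind, 5000, seed = 112)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(kendall_tau_empirical(xi[, i], xi[, j])), 0.03)
  # discrete margins are Poisson counts
  gtd <- build_ground_truth_vine(benchmark_case(4, "frank", "weak", "discrete"))
  xd <- generate_dataset(gtd, 2000, seed = 113)
  expect_true(all(xd >= 0 & xd == round(xd)))
  expect_lt(abs(mean(xd) - 5), 0.2)
})

test_that("the benchmark driver produces one row per pair copula and rep", {
  case <- benchmark_case(4, "independence", "weak", "continuous")
  res <- run_benchmark(list(case), n_train = 1200, n_eval = 2000, reps = 2,
                       seed = 114,
                       fit_cfg = list(margin_method = "empirical",
                                      hyper = list(n_layers = 1,
                                                   hidden_units = 8,
                                                   n_bins = 4),
                                      train = list(max_epochs = 25,
                                                   patience = 10)))
  expect_equal(nrow(res), 2 * 6)
  expect_setequal(unique(res$tree), 1:3)
  expect_true(all(c("kl_nats", "entropy_bits", "fit_seconds", "estimator")
                  %in% names(res)))
  # independence sanity: near-zero divergence and entropy
  expect_lt(median(res$kl_nats), 0.05)
  expect_lt(median(abs(res$entropy_bits)), 0.1)
})

test_that("benchmark aggregation summarizes cases and exports the scatter", {
  one <- data.frame(dim = 4, family = "clayton", strength = "weak",
                    data_type = "continuous", estimator = "nsf",
                    repetition = 1, tree = 1, pair = 1,
                    kl_nats = 0.07, entropy_bits = -0.5, fit_seconds = 1)
  agg1 <- aggregate_results(one)
  expect_equal(agg1$summary$kl_median, 0.07)
  expect_equal(nrow(agg1$summary), 1)
  two <- rbind(one, transform(one, family = "frank", kl_nats = 0.02))
  expect_equal(nrow(aggregate_results(two)$summary), 2)
  expect_equal(nrow(aggregate_results(two)$scatter), 2)
  expect_error(aggregate_results(one[0, ]), "empty")
})

test_that("the synthetic corridor fixture has the designed structure", {
  fx <- generate_v1_like_fixture(n_trials = 60, seed = 115)
  expect_identical(generate_v1_like_fixture(n_trials = 60, seed = 115)$events,
                   fx$events)
  expect_equal(fx$corridor_length_cm, 160)
  expect_equal(fx$reward_zone, c(120, 140))
  ev1 <- fx$events[fx$events$unit == 1, ]
  in_rz <- ev1$position_cm >= 120 & ev1$position_cm < 140
  # the reward-zone unit fires more per time step inside the zone
  expect_gt(mean(ev1$spikes[in_rz]), mean(ev1$spikes[!in_rz]))
  # licks concentrate in the reward zone and track the reward-zone unit
  b <- fx$behavior
  rz_b <- b$position_cm >= 120 & b$position_cm < 140
  expect_gt(mean(b$licks[rz_b]), 10 * mean(b$licks[!rz_b]))
  licks_tr <- tapply(b$licks, b$trial, sum)
  unit1_tr <- tapply(ev1$spikes, ev1$trial, sum)
  expect_gt(kendall_tau_empirical(unit1_tr, licks_tr), 0.2)
  # running speed anticorrelates with reward-zone spiking across trials
  speed_tr <- tapply(b$speed_cm_s, b$trial, mean)
  expect_lt(kendall_tau_empirical(unit1_tr, speed_tr), -0.1)
})
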