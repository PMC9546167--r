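test_that("copula specs validate their parameter domains", {
  expect_error(copula_spec("clayton", theta = -1), "invalid")
  expect_error(copula_spec("clayton"), "invalid")
  expect_error(copula_spec("frank", theta = 0), "invalid")
  expect_error(copula_spec("gaussian", rho = 1), "invalid")
  expect_error(copula_spec("gaussian", theta = 2), "invalid")
  expect_error(copula_spec("independence", theta = 1), "invalid")
  expect_s3_class(copula_spec("frank", theta = -4), "copula_spec")
})

test_that("copula CDFs match closed forms and uniform-margin boundaries", {
  expect_equal(copula_cdf(copula_spec("independence"), 0.3, 0.6), 0.18)
  expect_equal(copula_cdf(copula_spec("clayton", theta = 2), 0.5, 0.5),
               7^(-1 / 2), tolerance = 1e-10)
  for (spec in list(copula_spec("clayton", theta = 2),
                    copula_spec("frank", theta = 3),
                    copula_spec("gaussian", rho = 0.8),
                    copula_spec("independence"))) {
    expect_equal(copula_cdf(spec, 0.7, 1), 0.7, tolerance = 1e-6)
    expect_equal(copula_cdf(spec, 1, 0.4), 0.4, tolerance = 1e-6)
    expect_equal(copula_cdf(spec, 0.5, 0), 0)
    expect_equal(copula_cdf(spec, 0, 0.5), 0)
  }
})

test_that("copulas are 2-increasing on random rectangles", {
  set.seed(11)
  for (spec in list(copula_spec("clayton", theta = 5),
                    copula_spec("frank", theta = -4),
                    copula_spec("gaussian", rho = -0.6),
                    copula_spec("independence"))) {
    u <- matrix(sort(runif(40)), 2)
    v <- matrix(sort(runif(40)), 2)
    vol <- copula_cdf(spec, u[2, ], v[2, ]) - copula_cdf(spec, u[1, ], v[2, ]) -
      copula_cdf(spec, u[2, ], v[1, ]) + copula_cdf(spec, u[1, ], v[1, ])
    expect_true(all(vol >= -1e-10))
  }
})

test_that("copula densities match the mixed finite difference of the CDF", {
  g <- seq(0.05, 0.95, length.out = 12)
  eps <- 1e-4
  for (spec in list(copula_spec("clayton", theta = 2),
                    copula_spec("frank", theta = 3),
                    copula_spec("gaussian", rho = 0.4))) {
    for (u in g) for (v in g) {
      fd <- (copula_cdf(spec, u + eps, v + eps) -
             copula_cdf(spec, u + eps, v - eps) -
             copula_cdf(spec, u - eps, v + eps) +
             copula_cdf(spec, u - eps, v - eps)) / (4 * eps^2)
      expect_equal(copula_pdf(spec, u, v), fd, tolerance = 1e-3)
    }
  }
  expect_equal(copula_pdf(copula_spec("independence"), 0.2, 0.9), 1)
  expect_equal(copula_pdf(copula_spec("gaussian", rho = 0.8), 0.5, 0.5),
               1 / sqrt(1 - 0.64), tolerance = 1e-10)
})

test_that("h-functions match closed forms and the CDF derivative", {
  expect_equal(copula_hfunc(copula_spec("independence"), 0.3, 0.8), 0.3)
  expect_equal(copula_hfunc(copula_spec("clayton", theta = 2), 0.5, 0.5),
               8 * 7^(-3 / 2), tolerance = 1e-10)
  eps <- 1e-5
  set.seed(12)
  for (spec in list(copula_spec("clayton", theta = 5),
                    copula_spec("frank", theta = 7),
                    copula_spec("gaussian", rho = 0.8))) {
    u <- runif(30, 0.05, 0.95); v <- runif(30, 0.05, 0.95)
    fd <- (copula_cdf(spec, u, v + eps) - copula_cdf(spec, u, v - eps)) / (2 * eps)
    expect_equal(copula_hfunc(spec, u, v), fd, tolerance = 1e-4)
    expect_equal(copula_hfunc(spec, rep(0, 3), v[1:3]), rep(0, 3))
    expect_equal(copula_hfunc(spec, rep(1, 3), v[1:3]), rep(1, 3))
  }
})

test_that("inverse h-functions round-trip to 1e-8", {
  set.seed(13)
  p <- runif(100, 1e-3, 1 - 1e-3)
  v <- runif(100, 1e-3, 1 - 1e-3)
  for (spec in list(copula_spec("clayton", theta = 2),
                    copula_spec("frank", theta = 3),
                    copula_spec("frank", theta = -5),
                    copula_spec("gaussian", rho = 0.8),
                    copula_spec("independence"))) {
    u <- copula_hinv(spec, p, v)
    expect_true(all(u > 0 & u < 1))
    expect_equal(copula_hfunc(spec, u, v), p, tolerance = 1e-8)
  }
  # p -> 0 drives u -> 0
  probes <- copula_hinv(copula_spec("clayton", theta = 2),
                        c(1e-3, 1e-6, 1e-9, 1e-12), 0.5)
  expect_true(all(diff(probes) < 0))
  expect_lt(probes[4], 1e-3)
})

test_that("sampled Kendall tau matches the closed form for all study settings", {
  cases <- list(copula_spec("clayton", theta = 2),
                copula_spec("clayton", theta = 5),
                copula_spec("frank", theta = 3),
                copula_spec("frank", theta = 7),
                copula_spec("gaussian", rho = 0.4),
                copula_spec("gaussian", rho = 0.8),
                copula_spec("independence"))
  for (spec in cases) {
    uv <- copula_sample(spec, 8000, seed = 17)
    tau_hat <- kendall_tau_empirical(uv[, 1], uv[, 2])
    expect_lt(abs(tau_hat - copula_kendall_tau(spec)), 3 / sqrt(8000))
  }
  # reproducibility
  expect_identical(copula_sample(cases[[1]], 100, seed = 5),
                   copula_sample(cases[[1]], 100, seed = 5))
})

test_that("closed-form tau values are correct", {
  expect_equal(copula_kendall_tau(copula_spec("clayton", theta = 2)), 0.5)
  expect_equal(copula_kendall_tau(copula_spec("independence")), 0)
  expect_equal(copula_kendall_tau(copula_spec("gaussian", rho = 0.8)),
               2 / pi * asin(0.8))
  # Frank via independent Debye quadrature
  th <- 3
  d1 <- stats::integrate(function(t) t / expm1(t), 0, th)$value / th
  expect_equal(copula_kendall_tau(copula_spec("frank", theta = th)),
               1 - 4 / th * (1 - d1), tolerance = 1e-8)
  expect_equal(copula_kendall_tau(copula_spec("frank", theta = 3)), 0.307,
               tolerance = 1e-3)
  # negative dependence mirrors
  expect_equal(copula_kendall_tau(copula_spec("frank", theta = -3)),
               -copula_kendall_tau(copula_spec("frank", theta = 3)))
})

test_that("Frank and Gaussian copulas reduce to independence at tiny parameters", {
  g <- seq(0.05, 0.95, length.out = 10)
  grid <- expand.grid(u = g, v = g)
  ind <- copula_cdf(copula_spec("independence"), grid$u, grid$v)
  frk <- copula_cdf(copula_spec("frank", theta = 1e-4), grid$u, grid$v)
  gau <- copula_cdf(copula_spec("gaussian", rho = 1e-4), grid$u, grid$v)
  expect_lt(max(abs(frk - ind)), 1e-3)
  expect_lt(max(abs(gau - ind)), 1e-3)
})

test_that("specs serialize to and from JSON", {
  for (spec in list(copula_spec("clayton", theta = 2),
                    copula_spec("gaussian", rho = -0.3),
                    copula_spec("independence"))) {
    expect_equal(copula_spec_from_json(copula_spec_to_json(spec)), spec)
  }
})
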