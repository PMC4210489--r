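test_that("rate decomposition matches the algebra and round-trips", {
  d <- decompose_rates(0.05, 0)
  expect_equal(c(d$lambda, d$mu), c(0.05, 0))

  d2 <- decompose_rates(-0.05, 2)          # declining diversity
  expect_equal(c(d2$lambda, d2$mu), c(0.05, 0.10))

  set.seed(2)
  for (i in 1:20) {
    lam <- runif(1, 0.01, 1)
    mu <- runif(1, 0, 1.3) * lam
    rt <- compose_rates(lam, mu)
    back <- decompose_rates(rt$r, rt$tau)
    expect_equal(back$lambda, lam, tolerance = 1e-12)
    expect_equal(back$mu, mu, tolerance = 1e-12)
  }
})

test_that("inadmissible turnover/diversification pairs are rejected", {
  expect_error(decompose_rates(0.1, 1), "singular")
  expect_error(decompose_rates(0.1, 2), "inadmissible")
  expect_error(decompose_rates(-0.1, 0.5), "inadmissible")
  expect_error(decompose_rates(0.1, -0.2), "non-negative")
})

test_that("method-of-moments rate has the published closed forms", {
  # crown variant at epsilon = 0 reduces to log(N/2)/t
  expect_equal(mom_rate(2, 37, 0, "crown"), 0)
  expect_equal(mom_rate(20000, 180.05, 0, "crown"), log(10000) / 180.05,
               tolerance = 1e-12)
  expect_equal(mom_rate(20000, 180.05, 0, "crown"), 0.0511543,
               tolerance = 1e-6)
  # stem variant
  expect_equal(mom_rate(100, 10, 0, "stem"), log(100) / 10)
  expect_equal(mom_rate(100, 10, 0.5, "stem"), log(50.5) / 10)
  # strictly decreasing in epsilon
  eps <- seq(0, 0.95, by = 0.05)
  eps <- eps[eps < 1]
  for (variant in c("crown", "stem")) {
    r <- mom_rate(5000, 120, eps, variant)
    expect_true(all(diff(r) < 0))
  }
  expect_error(mom_rate(100, 10, 1), "epsilon")
})

test_that("diversity back-projection and sampling fraction follow the ratio formula", {
  expect_equal(project_diversity(100, 10, 1), 10)
  expect_equal(project_diversity(20000, 50, 0.0529), 20000 / (50 * 0.0529))
  expect_equal(project_diversity(100, 10, 0.05, method = "exponential"),
               100 * exp(-0.5))
  expect_error(project_diversity(100, 10, 0), "positive")

  expect_equal(sampling_fraction(200, 8000), 0.025)
  expect_equal(sampling_fraction(123, 123), 1.0)
  expect_error(sampling_fraction(200, 100), "more sampled")
})

test_that("sampling-fraction derivation chains the three steps and rounds up", {
  der <- derive_sampling_fraction(n_present = 20000, crown_age = 180.05,
                                  horizon = 50, k_lineages = 200,
                                  epsilon = c(0, 0.5, 0.9))
  expect_equal(nrow(der$table), 3)
  expect_equal(der$table$r, mom_rate(20000, 180.05, c(0, 0.5, 0.9)))
  expect_equal(der$table$n_horizon, 20000 / (50 * der$table$r))
  expect_equal(der$table$rho, 200 / der$table$n_horizon)
  expect_equal(der$rho_conservative, ceiling(max(der$table$rho) * 100) / 100)
})

test_that("AICc has the small-sample form and exceeds plain AIC", {
  nll <- 523.7
  for (k in c(2, 5, 8)) {
    val <- aicc(nll, k, 150)
    expect_equal(val, 2 * k + 2 * nll + 2 * k * (k + 1) / (150 - k - 1))
    expect_gt(val, 2 * k + 2 * nll)
  }
  expect_equal(aicc(10, 5, 6), Inf)
})
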