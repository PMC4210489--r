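test_that("propagators satisfy boundary conditions and probability bounds", {
  set.seed(31)
  for (i in 1:25) {
    mt <- random_model_and_times()
    ages <- c(0, sort(runif(30, 0, mt$crown)))
    pr <- bd_propagators(mt$model, ages)
    expect_true(all(pr$p0 >= 0 & pr$p0 <= 1))
    expect_true(all(is.finite(pr$logq)))
    expect_equal(pr$p0[1], 1 - mt$model$rho, tolerance = 1e-12)
    expect_equal(pr$logq[1], log(mt$model$rho), tolerance = 1e-12)
  }
  # no extinction, complete sampling: a lineage always leaves descendants
  m <- episodic_bd_model(lambda = 0.2, mu = 0, rho = 1)
  pr <- bd_propagators(m, seq(0, 80, by = 5))
  expect_true(all(pr$p0 == 0))
})

test_that("a shift with no rate change reduces to the constant-rate model", {
  bt <- bt_from_times(c(4, 3, 2, 1))
  m0 <- episodic_bd_model(lambda = 0.3, mu = 0.1, rho = 0.6)
  m1 <- episodic_bd_model(shift_times = 2, lambda = c(0.3, 0.3),
                          mu = c(0.1, 0.1), rho = 0.6)
  expect_equal(episodic_loglik(bt, m1), episodic_loglik(bt, m0),
               tolerance = 1e-10)
})

test_that("constant-rate complete-sampling pure birth matches the analytic density", {
  # with mu = 0, rho = 1: log L = sum_{i>=2}(log lambda - lambda x_i)
  #                              - 2 lambda x_1
  set.seed(13)
  for (i in 1:10) {
    lam <- runif(1, 0.05, 0.6)
    times <- c(5, sort(runif(sample(2:12, 1), 0, 5), decreasing = TRUE))
    bt <- bt_from_times(times)
    m <- episodic_bd_model(lambda = lam, mu = 0, rho = 1)
    analytic <- sum(log(lam) - lam * bt$times[-1]) - 2 * lam * bt$times[1]
    expect_equal(episodic_loglik(bt, m), analytic, tolerance = 1e-10)
  }
})

test_that("the critical case lambda = mu is continuous, not singular", {
  bt <- bt_from_times(c(4, 3, 2, 1))
  exact <- episodic_loglik(bt, episodic_bd_model(lambda = 0.2, mu = 0.2,
                                                 rho = 0.8))
  near <- episodic_loglik(bt, episodic_bd_model(lambda = 0.2,
                                                mu = 0.2 + 1e-7, rho = 0.8))
  expect_true(is.finite(exact))
  expect_equal(exact, near, tolerance = 1e-5)
})

test_that("closed-form likelihood agrees with the ODE integration path", {
  bt <- bt_from_times(c(4, 3, 2, 1))
  model <- episodic_bd_model(shift_times = 2.5, lambda = c(0.3, 0.5),
                             mu = c(0.1, 0.4), rho = 0.6)
  a <- episodic_loglik(bt, model)
  b <- episodic_loglik_ode(bt, model)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("the optimizer kernel equals the public likelihood", {
  set.seed(17)
  for (i in 1:30) {
    mt <- random_model_and_times()
    iv <- findInterval(mt$bt$times, mt$model$shift_times) + 1L
    core <- divshift:::eloglik_core(mt$bt$times, mt$bt$n,
                                    mt$model$shift_times, mt$model$lambda,
                                    mt$model$mu, mt$model$rho, iv)
    expect_equal(core, episodic_loglik(mt$bt, mt$model), tolerance = 1e-12)
    core_n <- divshift:::eloglik_core(mt$bt$times, mt$bt$n,
                                      mt$model$shift_times, mt$model$lambda,
                                      mt$model$mu, mt$model$rho, iv,
                                      conditioning = "crown_n")
    expect_equal(core_n,
                 episodic_loglik(mt$bt, mt$model, conditioning = "crown_n"),
                 tolerance = 1e-12)
  }
})

test_that("mass-extinction boundary survival maps the propagators", {
  bt <- bt_from_times(c(4, 3, 2, 1))
  # boundary survival 1 is the identity
  m_plain <- episodic_bd_model(shift_times = 2.5, lambda = c(0.3, 0.2),
                               mu = c(0.1, 0.05), rho = 0.7)
  m_one <- episodic_bd_model(shift_times = 2.5, lambda = c(0.3, 0.2),
                             mu = c(0.1, 0.05), rho = 0.7, boundary_rho = 1)
  expect_equal(episodic_loglik(bt, m_one), episodic_loglik(bt, m_plain))
  # with survival < 1 the likelihood changes and still matches the ODE path
  m_me <- episodic_bd_model(shift_times = 2.5, lambda = c(0.3, 0.2),
                            mu = c(0.1, 0.05), rho = 0.7, boundary_rho = 0.6)
  expect_false(isTRUE(all.equal(episodic_loglik(bt, m_me),
                                episodic_loglik(bt, m_plain))))
  expect_equal(episodic_loglik(bt, m_me), episodic_loglik_ode(bt, m_me),
               tolerance = 1e-6)
})

test_that("shift times at or beyond the crown age are rejected", {
  bt <- bt_from_times(c(4, 3, 2, 1))
  m <- episodic_bd_model(shift_times = 4, lambda = c(0.3, 0.5),
                         mu = c(0.1, 0.2), rho = 1)
  expect_error(episodic_loglik(bt, m), "crown")
})
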