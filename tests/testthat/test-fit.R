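test_that("constant-rate fit equals direct 2-parameter optimization", {
  set.seed(23)
  tr <- simulate_bd_tree(episodic_bd_model(lambda = 0.12, mu = 0.04,
                                           rho = 1), 50)
  bt <- branching_times(tr)
  fit <- fit_episodic(bt, 0, rho = 1)
  # independent direct maximization of the public likelihood
  direct <- optim(c(log(0.1), log(0.05)), function(th) {
    -episodic_loglik(bt, episodic_bd_model(lambda = exp(th[1]),
                                           mu = exp(th[2]), rho = 1))
  }, method = "L-BFGS-B", lower = log(c(1e-7, 1e-10)), upper = log(c(50, 50)),
  control = list(factr = 1e2))
  expect_equal(fit$neg_loglik, direct$value, tolerance = 1e-6)
  expect_equal(fit$k, 2L)
  expect_equal(fit$aicc, aicc(fit$neg_loglik, 2, length(bt$times)))
})

test_that("constant-rate simulations recover diversification and turnover", {
  set.seed(29)
  truth <- episodic_bd_model(lambda = 0.10, mu = 0.05, rho = 1)
  r_hat <- tau_hat <- numeric(200)
  for (i in 1:200) {
    tr <- simulate_bd_tree(truth, 60)
    fit <- fit_episodic(branching_times(tr), 0, rho = 1, n_starts = 2)
    rt <- compose_rates(fit$model$lambda, fit$model$mu)
    r_hat[i] <- rt$r
    tau_hat[i] <- rt$tau
  }
  expect_lt(abs(median(r_hat) - 0.05) / 0.05, 0.10)
  expect_lt(abs(median(tau_hat) - 0.5) / 0.5, 0.20)
})

test_that("model dimensions too large for the data are refused", {
  bt <- bt_from_times(c(5, 4, 3, 2, 1))
  expect_error(fit_episodic(bt, 2, rho = 1), "branching times")
})

test_that("sequential model comparison accepts by chi-squared LRT", {
  fits <- list(fit_result(0, 500.0, 300), fit_result(1, 490.0, 300),
               fit_result(2, 489.5, 300))
  cmp <- compare_models(fits, alpha = 0.05)
  expect_equal(cmp$lrt_stat[2], 20)
  expect_equal(cmp$df[2], 3)
  expect_equal(cmp$p_value[2], pchisq(20, 3, lower.tail = FALSE))
  expect_true(cmp$accepted[2])
  # third model tested against the accepted 1-shift model, not the null
  expect_equal(cmp$lrt_stat[3], 1)
  expect_false(cmp$accepted[3])
  expect_equal(attr(cmp, "selected_m"), 1L)
  # zero statistic gives p = 1
  cmp2 <- compare_models(list(fit_result(0, 500, 300),
                              fit_result(1, 500, 300)))
  expect_equal(cmp2$p_value[2], 1)
  expect_error(compare_models(list(fit_result(1, 5, 30),
                                   fit_result(0, 6, 30))), "increasing")
  expect_error(compare_models(list(fit_result(0, 5, 30),
                                   fit_result(1, 4, 40))), "different data")
})

test_that("posterior replication summarizes the selected model's parameters", {
  set.seed(37)
  truth <- episodic_bd_model(lambda = 0.15, mu = 0.05, rho = 1)
  trees <- replicate(12, simulate_bd_tree(truth, 40), simplify = FALSE)
  bts <- lapply(trees, branching_times)
  summ <- posterior_fit_summary(bts, max_shifts = 0, rho = 1, n_starts = 2)
  expect_equal(summ$n_trees, 12)
  expect_equal(summ$n_failed, 0)
  expect_equal(summ$modal_m, 0L)
  expect_true(all(c("r1", "tau1", "lambda1", "mu1") %in%
                    summ$summary$parameter))
  expect_true(all(summ$summary$se >= 0))
  # identical trees give zero standard error
  same <- posterior_fit_summary(bts[c(1, 1, 1)], max_shifts = 0, rho = 1,
                                n_starts = 2)
  expect_true(all(same$summary$se < 1e-6))
})
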