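test_that("pure-birth simulations hit the expected tip count", {
  set.seed(67)
  model <- episodic_bd_model(lambda = 0.15, mu = 0, rho = 1)
  n <- replicate(1000, ape::Ntip(simulate_bd_tree(model, 20,
                                                  condition = "survival")))
  expected <- 2 * exp(0.15 * 20)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("rho-thinning halves the expected retained tip count", {
  set.seed(71)
  full <- episodic_bd_model(lambda = 0.12, mu = 0.03, rho = 1)
  half <- episodic_bd_model(lambda = 0.12, mu = 0.03, rho = 0.5)
  n_full <- n_half <- numeric(300)
  for (i in 1:300) {
    seed_i <- 1000 + i
    set.seed(seed_i)
    n_full[i] <- ape::Ntip(simulate_bd_tree(full, 30, condition = "survival"))
    set.seed(seed_i)   # same underlying event stream, coupled thinning
    n_half[i] <- tryCatch(
      ape::Ntip(simulate_bd_tree(half, 30, condition = "survival")),
      error = function(e) NA)
  }
  ratio <- mean(n_half, na.rm = TRUE) / mean(n_full)
  expect_gt(ratio, 0.40)
  expect_lt(ratio, 0.62)
})

test_that("identical seeds give identical trees and characters", {
  model <- episodic_bd_model(shift_times = 10, lambda = c(0.2, 0.1),
                             mu = c(0.05, 0.02), rho = 0.8)
  recipe <- sim_recipe(model, crown_age = 25, n_trees = 3, age_jitter = 0.02,
                       q_char = 0.02, seed = 99L)
  b1 <- simulate_bundle(recipe)
  b2 <- simulate_bundle(recipe)
  expect_identical(lapply(b1$trees, ape::write.tree),
                   lapply(b2$trees, ape::write.tree))
  expect_identical(b1$characters, b2$characters)
  expect_identical(b1$redraws, b2$redraws)
})

test_that("simulated trees are ultrametric with the requested crown age", {
  set.seed(73)
  model <- episodic_bd_model(lambda = 0.2, mu = 0.08, rho = 0.7)
  for (i in 1:10) {
    tr <- simulate_bd_tree(model, 30, condition = "crown")
    expect_true(check_ultrametric(tr)$pass)
    expect_equal(max(ape::node.depth.edgelength(tr)), 30, tolerance = 1e-8)
    expect_gte(ape::Ntip(tr), 2)
  }
})

test_that("hopeless parameter regimes fail with a redraw error", {
  dying <- episodic_bd_model(lambda = 0.01, mu = 2, rho = 1)
  expect_error(simulate_bd_tree(dying, 50, max_redraws = 50L), "redraws")
})

test_that("character simulation is exact in its limits", {
  set.seed(79)
  tr <- simulate_bd_tree(episodic_bd_model(lambda = 0.25, mu = 0, rho = 1),
                         25)
  # q = 0: everything inherits the root state
  expect_true(all(simulate_character(tr, 0, root_state = 1L) == 1L))
  # saturation: state frequencies near 1/2 over many tips
  big <- simulate_bd_tree(episodic_bd_model(lambda = 0.35, mu = 0, rho = 1),
                          25, condition = "survival")
  reps <- replicate(ceiling(10000 / ape::Ntip(big)),
                    simulate_character(big, 50, root_state = 1L))
  freq <- mean(unlist(reps) == 0L)
  n_draws <- length(unlist(reps))
  expect_lt(abs(freq - 0.5), 4 * sqrt(0.25 / n_draws) + 0.01)
})

test_that("node-age jitter keeps trees ultrametric and parent-older ordering", {
  set.seed(83)
  tr <- simulate_bd_tree(episodic_bd_model(lambda = 0.2, mu = 0.05,
                                           rho = 1), 40)
  jit <- jitter_node_ages(tr, 0.05)
  expect_true(check_ultrametric(jit)$pass)
  expect_true(all(jit$edge.length >= 0))
  expect_false(isTRUE(all.equal(jit$edge.length, tr$edge.length)))
})

test_that("study fixture has the configured scale and truth record", {
  fx <- get_study_fixture()
  tips <- sapply(fx$trees, ape::Ntip)
  expect_true(all(tips >= fx$truth$tip_band[1] &
                    tips <= fx$truth$tip_band[2]))
  crowns <- sapply(fx$trees, function(tr)
    max(ape::node.depth.edgelength(tr)))
  expect_true(all(abs(crowns - 180) < 25))
  # ~3% of true horizon lineages are represented in the tree
  rep_frac <- sapply(seq_along(fx$trees), function(i) {
    tr <- extend_tips_ultrametric(fx$trees[[i]])
    k <- sum(branching_times(tr, tol = 1e-4)$times > 50) + 1
    k / fx$horizon_counts[i]
  })
  expect_gt(mean(rep_frac), 0.02)
  expect_lt(mean(rep_frac), 0.045)
  # truth record round-trips through JSON serialization
  dir <- tempfile()
  write_fixture(fx[c("trees", "characters", "truth")], dir)
  truth_back <- jsonlite::read_json(file.path(dir, "truth.json"),
                                    simplifyVector = TRUE)
  expect_equal(truth_back$r_old, fx$truth$r_old)
  expect_equal(truth_back$shift_age, fx$truth$shift_age)
  expect_equal(truth_back$rho_horizon, fx$truth$rho_horizon)
})

test_that("branching-age sampler matches the conditioned density shape", {
  set.seed(89)
  model <- episodic_bd_model(lambda = 0.3, mu = 0.15, rho = 0.5)
  draws <- rbranching_ages(20000, model, 30)
  expect_true(all(draws >= 0 & draws <= 30))
  # compare the empirical CDF against direct numeric integration
  pr <- bd_propagators(model, seq(0, 30, length.out = 3001))
  dens <- exp(log(pr$lambda) + pr$logq)
  cdf <- cumsum(dens) / sum(dens)
  at <- c(5, 10, 20)
  for (a in at) {
    expect_equal(mean(draws <= a), cdf[round(a / 30 * 3000) + 1],
                 tolerance = 0.02)
  }
})
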