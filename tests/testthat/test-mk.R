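test_that("transition matrix is stochastic with P(same) >= P(diff)", {
  for (q in c(0, 0.01, 0.5, 10)) {
    for (dt in c(0, 0.1, 5, 100)) {
      P <- mk_transition_matrix(q, dt)
      expect_equal(rowSums(P), c(1, 1))
      expect_true(all(diag(P) >= P[1, 2]))
    }
  }
  expect_error(mk_transition_matrix(-1, 1), "non-negative")
})

test_that("pruning matches brute-force enumeration on small trees", {
  set.seed(41)
  for (i in 1:12) {
    tr <- ape::rcoal(sample(3:6, 1))
    states <- setNames(sample(c(0L, 1L, NA), ape::Ntip(tr), replace = TRUE,
                              prob = c(0.45, 0.45, 0.1)), tr$tip.label)
    if (sum(!is.na(states)) < 2) next
    q <- runif(1, 0.01, 3)
    expect_equal(mk_loglik(tr, states, q), mk_loglik_enum(tr, states, q),
                 tolerance = 1e-10)
  }
})

test_that("likelihood limits: q -> 0 and saturation", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  both0 <- setNames(c(0L, 0L), c("A", "B"))
  expect_equal(mk_loglik(tr, both0, 1e-12), log(0.5), tolerance = 1e-9)
  # incompatible data at q = 0 give likelihood zero, handled as -Inf
  mixed <- setNames(c(0L, 1L), c("A", "B"))
  expect_identical(mk_loglik(tr, mixed, 0), -Inf)
  # saturation: every tip independently uniform
  set.seed(43)
  tr2 <- ape::rcoal(9)
  states <- setNames(sample(0:1, 9, replace = TRUE), tr2$tip.label)
  expect_equal(mk_loglik(tr2, states, 1e4), 9 * log(0.5), tolerance = 1e-6)
})

test_that("rate estimation recovers the simulating rate and flags boundaries", {
  set.seed(47)
  tr <- simulate_bd_tree(episodic_bd_model(lambda = 0.12, mu = 0, rho = 1),
                         45)
  ok <- 0
  for (rep in 1:12) {
    states <- simulate_character(tr, q = 0.05, root_state = 1L)
    if (length(unique(states)) < 2) next
    f <- fit_mk(tr, states)
    if (f$q > 0.05 / 2.5 && f$q < 0.05 * 2.5) ok <- ok + 1
  }
  expect_gt(ok, 6)
  # all tips identical: boundary at q = 0
  same <- setNames(rep(1L, ape::Ntip(tr)), tr$tip.label)
  f0 <- fit_mk(tr, same)
  expect_true(f0$boundary)
  expect_lt(f0$q, 1e-6)
  expect_error(fit_mk(tr, setNames(rep(NA, ape::Ntip(tr)), tr$tip.label)),
               "missing")
})

test_that("rate estimate and likelihood agree with an independent Mk fitter", {
  set.seed(97)
  tr <- simulate_bd_tree(episodic_bd_model(lambda = 0.1, mu = 0, rho = 1),
                         50)
  states <- simulate_character(tr, q = 0.03, root_state = 1L)
  f <- fit_mk(tr, states)
  ref <- phytools::fitMk(tr, setNames(as.character(states), names(states)),
                         model = "ER", pi = "equal")
  expect_equal(f$q, ref$rates, tolerance = 1e-3)
  expect_equal(f$loglik, ref$logLik, tolerance = 1e-5)
})

test_that("fit is invariant under tip relabeling/reordering", {
  set.seed(53)
  tr <- ape::rcoal(10)
  states <- setNames(sample(0:1, 10, replace = TRUE), tr$tip.label)
  f1 <- fit_mk(tr, states)
  perm <- sample(10)
  tr2 <- tr
  tr2$tip.label <- paste0("x", tr$tip.label)
  states2 <- setNames(states[perm], paste0("x", names(states)[perm]))
  f2 <- fit_mk(tr2, states2)
  expect_equal(f1$q, f2$q, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("marginal reconstruction satisfies the exact marginalization identity", {
  set.seed(59)
  for (i in 1:8) {
    tr <- ape::rcoal(sample(4:12, 1))
    states <- setNames(sample(0:1, ape::Ntip(tr), replace = TRUE),
                       tr$tip.label)
    q <- runif(1, 0.05, 2)
    asr <- marginal_asr(tr, states, q)
    lse <- apply(cbind(asr$lnL_other, asr$lnL_arid), 1, function(z) {
      mx <- max(z)
      mx + log(sum(exp(z - mx)))
    })
    expect_equal(lse, rep(attr(asr, "total_loglik"), nrow(asr)),
                 tolerance = 1e-10)
    expect_equal(attr(asr, "total_loglik"), mk_loglik(tr, states, q),
                 tolerance = 1e-10)
  }
})

test_that("marginal state likelihoods match enumeration with a fixed node", {
  set.seed(61)
  tr <- ape::rcoal(5)
  states <- setNames(c(1L, 0L, 1L, 1L, 0L), tr$tip.label)
  q <- 0.4
  asr <- marginal_asr(tr, states, q)
  for (i in seq_len(nrow(asr))) {
    expect_equal(asr$lnL_other[i],
                 mk_loglik_enum(tr, states, q, asr$node[i], 0L),
                 tolerance = 1e-10)
    expect_equal(asr$lnL_arid[i],
                 mk_loglik_enum(tr, states, q, asr$node[i], 1L),
                 tolerance = 1e-10)
  }
})

test_that("two-tip symmetric case is exactly ambiguous", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  asr <- marginal_asr(tr, setNames(c(0L, 1L), c("A", "B")), 0.3)
  expect_equal(asr$delta_lnl, 0)
  expect_equal(asr$call, "ambiguous")
})

test_that("character tables round-trip and prune-to-group is deterministic", {
  f <- tempfile(fileext = ".tsv")
  states <- setNames(c(1L, 0L, NA), c("gA_sp1", "gA_sp2", "gB_sp1"))
  write_character_table(states, f, header = "unit test")
  back <- read_character_table(f)
  expect_equal(divshift:::coerce_states(back), states)

  tr <- ape::read.tree(text = "((gA_sp1:1,gA_sp2:1):1,gB_sp1:2);")
  genus <- setNames(c("gA", "gA", "gB"), names(states))
  miss <- setNames(c(0, 1, 0), names(states))
  pruned <- prune_to_one_per_group(tr, genus, miss)
  expect_setequal(pruned$tip.label, c("gA", "gB"))
  # gA_sp1 kept (fewest missing); ties broken lexicographically
  pruned2 <- prune_to_one_per_group(tr, genus)
  expect_setequal(pruned2$tip.label, c("gA", "gB"))
})
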