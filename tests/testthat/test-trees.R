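test_that("newick and NEXUS files are read with labels and ages intact", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", nwk)
  trees <- read_trees(nwk)
  expect_length(trees, 1)
  expect_equal(ape::Ntip(trees[[1]]), 3)
  expect_equal(max(ape::node.depth.edgelength(trees[[1]])), 2.0)

  nex <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN TREES;",
               "  TRANSLATE", "    1 Alpha,", "    2 Beta,", "    3 Gamma;",
               "  TREE one = ((1:1,2:1):1,3:2);",
               "  TREE two = ((1:2,3:2):1,2:3);",
               "END;"), nex)
  trees2 <- read_trees(nex)
  expect_length(trees2, 2)
  expect_setequal(trees2[[1]]$tip.label, c("Alpha", "Beta", "Gamma"))
  expect_equal(max(ape::node.depth.edgelength(trees2[[2]])), 3.0)
})

test_that("malformed newick is rejected, not partially parsed", {
  bad <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2", bad)
  expect_error(read_trees(bad))
})

test_that("write -> read round-trip preserves topology and ages", {
  set.seed(42)
  for (i in 1:5) {
    tr <- ape::rcoal(sample(4:30, 1))
    f <- tempfile(fileext = ".nwk")
    ape::write.tree(tr, f)
    back <- read_trees(f)[[1]]
    expect_equal(ape::Ntip(back), ape::Ntip(tr))
    d1 <- sort(ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))])
    d2 <- sort(ape::node.depth.edgelength(back)[seq_len(ape::Ntip(back))])
    expect_equal(d1, d2, tolerance = 1e-9)
    expect_true(ape::all.equal.phylo(back, tr, use.edge.length = FALSE))
  }
})

test_that("ultrametricity check reports deviations and tolerates jitter", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  chk <- check_ultrametric(t1)
  expect_true(chk$pass)
  expect_equal(chk$max_deviation, 0)

  t2 <- ape::read.tree(text = "((A:1,B:1.2):1,C:2);")
  chk2 <- check_ultrametric(t2)
  expect_false(chk2$pass)
  expect_equal(chk2$max_deviation, 0.2, tolerance = 1e-12)
  expect_equal(chk2$bad_tips, "B")

  t3 <- t1
  tip_edges <- t3$edge[, 2] <= 3
  t3$edge.length[tip_edges] <- t3$edge.length[tip_edges] +
    c(1e-9, -1e-9, 5e-10)
  expect_true(check_ultrametric(t3)$pass)
})

test_that("polytomies are rejected by default and resolvable on request", {
  f <- tempfile(fileext = ".nwk")
  writeLines("(A:2,B:2,C:2);", f)
  expect_error(read_trees(f), "polytom")
  tr <- read_trees(f, resolve_polytomies = TRUE)[[1]]
  expect_true(ape::is.binary(tr))
  expect_equal(ape::Ntip(tr), 3)
})

test_that("branching times are the descending internal-node ages", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  bt <- branching_times(t1)
  expect_equal(bt$times, c(2, 1))
  expect_equal(bt$n, 3L)
  expect_equal(bt$t_cut, 0)

  t2 <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  expect_equal(branching_times(t2)$times, c(2, 1.5, 1))

  set.seed(7)
  tr <- ape::rcoal(40)
  bt2 <- branching_times(tr)
  expect_length(bt2$times, 39)
  expect_equal(bt2$times[1], max(ape::node.depth.edgelength(tr)),
               tolerance = 1e-9)
  expect_error(branching_times(ape::read.tree(text = "((A:1,B:1.5):1,C:2);")),
               "ultrametric")
})

test_that("truncation re-bases the age axis and counts crossing lineages", {
  bt <- bt_from_times(c(2, 1))
  cut1 <- truncate_at(bt, 0.5)
  expect_equal(cut1$times, c(1.5, 0.5))
  expect_equal(cut1$n, 3L)
  expect_equal(cut1$t_cut, 0.5)

  cut2 <- truncate_at(bt, 1.5)
  expect_equal(cut2$times, 0.5)
  expect_equal(cut2$n, 2L)

  expect_error(truncate_at(bt, 2.5), "crown")
  expect_identical(truncate_at(bt, 0), bt)
})

test_that("truncation composes additively", {
  set.seed(3)
  for (i in 1:10) {
    bt <- bt_from_times(c(10, runif(15, 0, 10)))
    a <- runif(1, 0, 4)
    b <- runif(1, 0, 4)
    two_step <- truncate_at(truncate_at(bt, a), b)
    one_step <- truncate_at(bt, a + b)
    expect_equal(two_step$times, one_step$times, tolerance = 1e-12)
    expect_equal(two_step$n, one_step$n)
    expect_equal(two_step$t_cut, one_step$t_cut)
  }
})

test_that("LTT curve is a unit-step function with n lineages at the present", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  curve <- ltt_curve(t1)
  expect_equal(ltt_at(curve, c(0, 0.5, 1.5, 2, 3)), c(3L, 3L, 2L, 1L, 1L))

  set.seed(11)
  tr <- ape::rcoal(25)
  cv <- ltt_curve(tr)
  expect_equal(cv$lineages[nrow(cv)], 25)
  expect_true(all(diff(cv$lineages[-nrow(cv)]) == 1))   # unit steps
  ages <- sort(runif(20, 0, max(cv$age)))
  counts <- ltt_at(cv, ages)
  expect_true(all(diff(counts[order(ages)]) <= 0))      # non-increasing in age
})

test_that("median LTT equals the brute-force pointwise median", {
  set.seed(5)
  trees <- lapply(1:101, function(i) ape::rcoal(sample(5:40, 1)))
  curves <- lapply(trees, ltt_curve)
  grid_ages <- seq(0, max(sapply(curves, function(cv) max(cv$age))),
                   length.out = 41)
  med <- median_ltt(curves, grid_ages)
  brute <- sapply(grid_ages, function(a) {
    median(sapply(curves, function(cv) ltt_at(cv, a)))
  })
  expect_equal(med$lineages, brute)
  # median of identical curves is that curve
  same <- median_ltt(curves[c(1, 1, 1)], grid_ages)
  expect_equal(same$lineages, as.numeric(ltt_at(curves[[1]], grid_ages)))
  expect_error(median_ltt(list(), grid_ages), "empty")
})
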