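# Forward (Gillespie-style) simulation of reconstructed trees under an
# episodic birth-death process with rho-sampling at the present, plus the
# character simulator and node-age jitter used to emulate a posterior sample
# of chronograms.

#' Simulation recipe
#'
#' Bundles everything needed to generate a replicate set of synthetic
#' chronograms with a binary character: the generating episodic birth-death
#' model, the crown age, the number of replicates, the node-age jitter
#' emulating posterior dating spread, and the Mk character truth. The seed
#' fully determines all outputs.
#'
#' @param model An \code{episodic_bd} truth model (its \code{rho} is the
#'   sampling fraction applied at the present).
#' @param crown_age Crown age (Myr): the simulated span.
#' @param n_trees Number of replicate trees.
#' @param age_jitter Fractional (lognormal sigma) node-age jitter; 0 disables.
#' @param q_char,root_state Mk character truth (rate per Myr, root state
#'   0/1).
#' @param seed Integer seed.
#' @param condition \code{"crown"} (default): redraw until both original
#'   crown lineages have sampled descendants, so the crown age of the output
#'   equals \code{crown_age}; \code{"survival"}: only require >= 2 sampled
#'   tips (the crown age may then be younger than the span).
#' @param max_redraws Redraw budget per accepted tree.
#' @return A list of class \code{sim_recipe}.
#' @export
sim_recipe <- function(model, crown_age, n_trees = 1L, age_jitter = 0,
                       q_char = 0.01, root_state = 1L, seed = 1L,
                       condition = c("crown", "survival"),
                       max_redraws = 10000L) {
  condition <- match.arg(condition)
  stopifnot(inherits(model, "episodic_bd"), crown_age > 0, n_trees >= 1)
  if (model$m > 0 && any(model$shift_times >= crown_age))
    stop("shift times must lie inside the simulated span")
  structure(list(model = model, crown_age = crown_age,
                 n_trees = as.integer(n_trees), age_jitter = age_jitter,
                 q_char = q_char, root_state = as.integer(root_state),
                 seed = as.integer(seed), condition = condition,
                 max_redraws = as.integer(max_redraws)),
            class = "sim_recipe")
}

# One forward pass: event-driven birth-death from 2 crown lineages over
# [crown_age, 0] with rates switching at the model's shift ages. Returns
# per-lineage records (parent, birth/end age, fate) or NULL if all lineages
# die before the present.
forward_bd_pass <- function(model, crown_age) {
  n_max <- 256L
  parent <- integer(n_max)
  birth <- numeric(n_max)
  end <- numeric(n_max)
  fate <- integer(n_max)      # 0 alive at present, 1 split, 2 extinct
  child1 <- integer(n_max)
  child2 <- integer(n_max)
  n_rec <- 2L
  parent[1:2] <- 0L
  birth[1:2] <- crown_age
  alive <- c(1L, 2L)
  n_alive <- 2L
  # age boundaries at which rates change, descending
  bounds <- sort(model$shift_times[model$shift_times < crown_age],
                 decreasing = TRUE)
  a <- crown_age
  repeat {
    iv <- findInterval(a - 1e-12, model$shift_times) + 1L
    lam <- model$lambda[iv]
    mu <- model$mu[iv]
    next_bound <- if (length(bounds) && bounds[1] < a) bounds[1] else 0
    while (a > next_bound) {
      if (n_alive == 0L) return(NULL)
      w <- stats::rexp(1L, n_alive * (lam + mu))
      if (a - w <= next_bound) {
        a <- next_bound
        break
      }
      a <- a - w
      idx <- if (n_alive == 1L) 1L else sample.int(n_alive, 1L)
      lin <- alive[idx]
      if (stats::runif(1L) < lam / (lam + mu)) {
        # split: retire lin, add two daughters
        if (n_rec + 2L > n_max) {
          n_max <- n_max * 2L
          length(parent) <- n_max; length(birth) <- n_max
          length(end) <- n_max; length(fate) <- n_max
          length(child1) <- n_max; length(child2) <- n_max
          parent[is.na(parent)] <- 0L
        }
        end[lin] <- a; fate[lin] <- 1L
        c1 <- n_rec + 1L; c2 <- n_rec + 2L
        parent[c1] <- lin; parent[c2] <- lin
        birth[c1] <- a; birth[c2] <- a
        n_rec <- n_rec + 2L
        alive[idx] <- c1
        n_alive <- n_alive + 1L
        alive[n_alive] <- c2
      } else {
        end[lin] <- a; fate[lin] <- 2L
        alive[idx] <- alive[n_alive]
        n_alive <- n_alive - 1L
      }
    }
    if (n_alive == 0L) return(NULL)
    if (next_bound == 0) break
    bounds <- bounds[-1]
    a <- next_bound
  }
  survivors <- alive[seq_len(n_alive)]
  end[survivors] <- 0
  fate[survivors] <- 0L
  list(parent = parent[seq_len(n_rec)], birth = birth[seq_len(n_rec)],
       end = end[seq_len(n_rec)], fate = fate[seq_len(n_rec)],
       survivors = survivors)
}

# Reconstructed tree (newick) from a forward pass given the set of sampled
# survivor lineage ids. Unary chains are suppressed; tip labels t<lineage id>.
# tip_render(id, top_age) may override how a sampled tip's branch (starting
# at top_age, ending at age 0) is written, e.g. to graft a subtree.
reconstruct_newick <- function(pass, sampled, tip_render = NULL) {
  n <- length(pass$parent)
  has_sample <- logical(n)
  has_sample[sampled] <- TRUE
  # children recorded after parents, so a reverse sweep propagates upward
  for (i in n:1) {
    if (has_sample[i] && pass$parent[i] > 0L)
      has_sample[pass$parent[i]] <- TRUE
  }
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pass$parent[i]
    if (p > 0L && has_sample[i]) kids[[p]] <- c(kids[[p]], i)
  }
  is_tip <- logical(n)
  is_tip[sampled] <- TRUE
  # subtree(i, top_age): newick for the sampled subtree of lineage i whose
  # branch starts at top_age
  subtree <- function(i, top_age) {
    repeat {
      if (is_tip[i])
        return(if (is.null(tip_render)) sprintf("t%d:%.10g", i, top_age)
               else tip_render(i, top_age))
      k <- kids[[i]]
      if (length(k) == 2L) {
        split_age <- pass$end[i]
        return(sprintf("(%s,%s):%.10g",
                       subtree(k[1], split_age), subtree(k[2], split_age),
                       top_age - split_age))
      }
      i <- k[1]   # unary pass-through: keep descending, same branch
    }
  }
  roots <- which(pass$parent == 0L & has_sample)
  if (length(roots) == 2L) {
    crown <- pass$birth[1]
    sprintf("(%s,%s);", subtree(roots[1], crown), subtree(roots[2], crown))
  } else {
    # single surviving side: collapse to its earliest sampled-ancestor split
    i <- roots[1]
    while (!is_tip[i] && length(kids[[i]]) == 1L) i <- kids[[i]][1]
    if (is_tip[i]) return(NULL)   # fewer than 2 sampled tips
    split_age <- pass$end[i]
    k <- kids[[i]]
    sprintf("(%s,%s);", subtree(k[1], split_age), subtree(k[2], split_age))
  }
}

#' Simulate a reconstructed chronogram under an episodic birth-death model
#'
#' Event-driven forward simulation from two crown lineages with
#' piecewise-constant rates; extinct lineages are pruned, each survivor at
#' the present is retained independently with probability \code{rho}, and
#' trees leaving fewer than 2 sampled tips (or, under crown conditioning, a
#' lost crown lineage) are discarded and redrawn. The redraw count is
#' recorded in attribute \code{"redraws"}.
#'
#' @param model An \code{episodic_bd} truth model (\code{rho} applied at the
#'   present).
#' @param crown_age Simulated span (Myr).
#' @param condition \code{"crown"}: both original crown lineages must have
#'   sampled descendants (the returned crown age equals \code{crown_age});
#'   \code{"survival"}: any tree with >= 2 sampled tips is accepted.
#' @param max_redraws Redraw budget before erroring out.
#' @return An ultrametric \code{phylo} with attribute \code{"redraws"}.
#' @export
simulate_bd_tree <- function(model, crown_age,
                             condition = c("crown", "survival"),
                             max_redraws = 10000L) {
  condition <- match.arg(condition)
  stopifnot(inherits(model, "episodic_bd"))
  for (attempt in seq_len(max_redraws)) {
    pass <- forward_bd_pass(model, crown_age)
    if (is.null(pass)) next
    sampled <- pass$survivors[stats::runif(length(pass$survivors)) <= model$rho]
    if (length(sampled) < 2L) next
    if (condition == "crown") {
      # both crown lineages (records 1 and 2) must have sampled descendants
      anc <- function(i) {
        while (pass$parent[i] > 0L) i <- pass$parent[i]
        i
      }
      sides <- unique(vapply(sampled, anc, integer(1)))
      if (length(sides) < 2L) next
    }
    nwk <- reconstruct_newick(pass, sampled)
    if (is.null(nwk)) next
    tree <- ape::read.tree(text = nwk)
    attr(tree, "redraws") <- attempt - 1L
    return(tree)
  }
  stop("no acceptable tree in ", max_redraws, " redraws; ",
       "survival probability too low under these parameters")
}

#' Simulate a binary character on a tree under the symmetric Mk model
#'
#' States evolve independently along each branch; for the symmetric 2-state
#' process the transition kernel over a branch of length \code{dt} is exactly
#' \code{P(change) = (1 - exp(-2 q dt))/2} (the marginal of exponentially
#' distributed flip events), which is drawn directly.
#'
#' @param tree A \code{phylo} tree.
#' @param q Symmetric flip rate per Myr.
#' @param root_state Root state (0/1).
#' @return Named integer vector of tip states.
#' @export
simulate_character <- function(tree, q, root_state = 1L) {
  if (q < 0) stop("rate q must be non-negative")
  topo <- tree_topology(tree)
  ntip <- ape::Ntip(tree)
  state <- integer(ntip + tree$Nnode)
  state[topo$root] <- as.integer(root_state)
  for (v in rev(topo$postorder_nodes)) {
    key <- as.character(v)
    kids <- topo$children[[key]]
    lens <- topo$branch[[key]]
    p_change <- 0.5 * (1 - exp(-2 * q * lens))
    flip <- stats::runif(length(kids)) < p_change
    state[kids] <- ifelse(flip, 1L - state[v], state[v])
  }
  stats::setNames(state[seq_len(ntip)], tree$tip.label)
}

#' Jitter node ages to emulate posterior dating spread
#'
#' Multiplies every internal-node age by an independent lognormal factor
#' (median 1), then restores parent-older-than-child ordering by clamping
#' each child age just below its parent's going root-to-tip. Tips stay at
#' age 0. A pragmatic stand-in for dating uncertainty, not a model of a
#' relaxed-clock posterior.
#'
#' @param tree An ultrametric \code{phylo}.
#' @param sd Lognormal sigma of the age multiplier; 0 returns the tree
#'   unchanged.
#' @return The jittered ultrametric tree.
#' @export
jitter_node_ages <- function(tree, sd = 0.02) {
  if (sd == 0) return(tree)
  ntip <- ape::Ntip(tree)
  topo <- tree_topology(tree)
  ages <- node_ages(tree)
  ages[(ntip + 1):(ntip + tree$Nnode)] <-
    ages[(ntip + 1):(ntip + tree$Nnode)] *
    exp(stats::rnorm(tree$Nnode, 0, sd))
  ages[seq_len(ntip)] <- 0
  for (v in rev(topo$postorder_nodes)) {     # preorder: parents first
    kids <- topo$children[[as.character(v)]]
    internal_kids <- kids[kids > ntip]
    if (length(internal_kids))
      ages[internal_kids] <- pmin(ages[internal_kids], ages[v] * (1 - 1e-9))
  }
  edge_parent <- tree$edge[, 1]
  edge_child <- tree$edge[, 2]
  tree$edge.length <- ages[edge_parent] - ages[edge_child]
  tree
}

#' Generate a replicate set of chronograms with characters from a recipe
#'
#' @param recipe A \code{sim_recipe}.
#' @return A list of class \code{sim_bundle}: \code{trees} (multiPhylo),
#'   \code{characters} (list of named state vectors), \code{redraws}
#'   (per-tree counts), and \code{truth} (the recipe).
#' @export
simulate_bundle <- function(recipe) {
  stopifnot(inherits(recipe, "sim_recipe"))
  set.seed(recipe$seed)
  trees <- vector("list", recipe$n_trees)
  chars <- vector("list", recipe$n_trees)
  redraws <- integer(recipe$n_trees)
  for (i in seq_len(recipe$n_trees)) {
    tr <- simulate_bd_tree(recipe$model, recipe$crown_age,
                           condition = recipe$condition,
                           max_redraws = recipe$max_redraws)
    redraws[i] <- attr(tr, "redraws")
    if (recipe$age_jitter > 0) tr <- jitter_node_ages(tr, recipe$age_jitter)
    trees[[i]] <- tr
    chars[[i]] <- simulate_character(tr, recipe$q_char, recipe$root_state)
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, characters = chars, redraws = redraws,
                 truth = recipe),
            class = "sim_bundle")
}

#' Draw branching-time ages from the conditioned interior density
#'
#' Inverse-CDF sampling from the density proportional to
#' \code{lambda(u) q(u)} on \code{(0, max_age)}: the distribution of interior
#' branching times of a reconstructed tree under the episodic birth-death
#' model conditioned on the crown age. Serves as the distributional oracle
#' for validating the forward simulator against the likelihood, and to build
#' reconstructed subtrees directly.
#'
#' @param n Number of draws.
#' @param model An \code{episodic_bd} model.
#' @param max_age Upper age bound (crown age), Myr.
#' @param grid_n Grid resolution for the numeric CDF inversion.
#' @return Numeric vector of ages in \code{(0, max_age)}.
#' @export
rbranching_ages <- function(n, model, max_age, grid_n = 20001L) {
  u <- seq(0, max_age, length.out = grid_n)
  pr <- bd_propagators(model, u)
  dens <- exp(log(pr$lambda) + pr$logq)
  cdf <- cumsum(c(0, (dens[-1] + dens[-grid_n]) / 2 * diff(u)))
  cdf <- cdf / cdf[grid_n]
  stats::approx(cdf, u, xout = stats::runif(n), ties = "ordered")$y
}
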