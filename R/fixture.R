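# Synthetic study fixture: a replicate sample of chronograms emulating the
# posterior tree sample the diversification analysis consumes. Each tree has
# a crown age of ~180 Myr, one diversification shift at 103 Ma (older
# interval r = 0.085, tau = 0.305; younger interval r = 0.022, tau = 0.935),
# and is sampled so that ~3% of the true lineages at the 50 Ma analysis
# horizon leave sampled present-day descendants, with ~250 tips at the
# present.
#
# Construction: the episodic process is simulated forward (event-driven)
# from two crown lineages down to the 50 Ma horizon. The Cenozoic fate of
# each horizon lineage is then drawn from the exact distribution a constant-
# rate birth-death process with present-day sampling implies: the number of
# sampled descendants is zero-inflated geometric, and a surviving lineage's
# reconstructed subtree has i.i.d. coalescent ages with density proportional
# to lambda*q(u) and ranked-uniform topology. The Cenozoic rates and
# present-day sampling fraction are solved so that (i) the probability that
# a horizon lineage leaves sampled descendants is the target horizon
# sampling fraction (0.03) and (ii) the expected number of present-day tips
# is the target tip count (250), with the present-day sampling fraction
# fixed at 250/20000 (sampled richness over total standing richness).

#' Parameters of the synthetic study fixture
#'
#' @param crown_age Crown age, Myr (default 180).
#' @param horizon Analysis horizon, Myr before present (default 50).
#' @param shift_age Shift age, Myr before present (default 103).
#' @param r_old,tau_old Net diversification and turnover of the pre-shift
#'   (older) interval.
#' @param r_young,tau_young Same for the post-shift (younger) interval
#'   between the shift and the horizon.
#' @param rho_horizon Fraction of true horizon lineages represented in the
#'   tree (default 0.03).
#' @param n_tips_target Expected present-day tip count (default 250).
#' @param n_present Standing present-day richness used to fix the
#'   present-day sampling fraction (default 20000).
#' @param tip_band Accepted range of present-day tip counts; trees outside
#'   it are redrawn (default roughly +/-35% around the target, emulating a
#'   posterior sample of a single dataset of fixed size).
#' @param q_char,root_state Mk character truth (default: strong conservatism
#'   q = 0.003 per Myr, arid root).
#' @param age_jitter Lognormal node-age jitter sigma (default 0.02).
#' @return A list of class \code{fixture_params}; includes the derived
#'   Cenozoic rates \code{lambda_recent}, \code{mu_recent} and present-day
#'   sampling fraction \code{rho_present}.
#' @export
fixture_params <- function(crown_age = 180, horizon = 50, shift_age = 103,
                           r_old = 0.085, tau_old = 0.305,
                           r_young = 0.022, tau_young = 0.935,
                           rho_horizon = 0.03, n_tips_target = 250,
                           n_present = 20000,
                           tip_band = c(160, 340),
                           q_char = 0.003, root_state = 1L,
                           age_jitter = 0.02) {
  old <- decompose_rates(r_old, tau_old)
  yng <- decompose_rates(r_young, tau_young)
  span <- crown_age - horizon
  shift_rel <- shift_age - horizon
  horizon_model <- episodic_bd_model(
    shift_times = shift_rel,
    lambda = c(yng$lambda, old$lambda), mu = c(yng$mu, old$mu), rho = 1)
  # True horizon descendant count of one crown lineage: zero-inflated
  # geometric (p0T extinct by the horizon; mean e_k). Retained trees are
  # conditioned on both crown lineages leaving sampled descendants, which
  # size-biases the horizon counts, so the tip-count target must be hit
  # under that conditional law, not the unconditional one.
  e_k <- exp(r_old * (span - shift_rel) + r_young * shift_rel)
  p0T <- bd_propagators(horizon_model, span)$p0
  betaT <- 1 - (1 - p0T) / e_k
  s <- rho_horizon              # per-horizon-lineage sampled-survival prob
  cc <- 1 - s
  # P(crown side sampled-survives) and E[true horizon count | it does]
  p_side <- (1 - p0T) * (1 - (1 - betaT) * cc / (1 - betaT * cc))
  e_k_surv <- (1 - p0T) * (1 - betaT) *
    (1 / (1 - betaT)^2 - cc / (1 - betaT * cc)^2) / p_side
  e_horizon <- 2 * e_k_surv     # conditioned expected true horizon lineages
  rho_present <- n_tips_target / n_present
  # expected sampled present-day tips per true horizon lineage
  e_tips_per_lineage <- n_tips_target / e_horizon
  delta_recent <- log(e_tips_per_lineage / rho_present) / horizon
  # solve for the recent speciation rate such that the probability a horizon
  # lineage leaves a sampled descendant equals rho_horizon
  surv_prob <- function(lambda) {
    mu <- lambda - delta_recent
    mdl <- episodic_bd_model(lambda = lambda, mu = mu, rho = rho_present)
    1 - bd_propagators(mdl, horizon)$p0
  }
  lambda_recent <- stats::uniroot(function(l) surv_prob(l) - rho_horizon,
                                  lower = delta_recent + 1e-6, upper = 5,
                                  tol = 1e-12)$root
  mu_recent <- lambda_recent - delta_recent
  structure(list(crown_age = crown_age, horizon = horizon,
                 shift_age = shift_age,
                 r_old = r_old, tau_old = tau_old,
                 r_young = r_young, tau_young = tau_young,
                 lambda_old = old$lambda, mu_old = old$mu,
                 lambda_young = yng$lambda, mu_young = yng$mu,
                 rho_horizon = rho_horizon, n_tips_target = n_tips_target,
                 n_present = n_present, tip_band = tip_band,
                 lambda_recent = lambda_recent, mu_recent = mu_recent,
                 rho_present = rho_present, e_horizon = e_horizon,
                 q_char = q_char, root_state = as.integer(root_state),
                 age_jitter = age_jitter,
                 horizon_model = horizon_model),
            class = "fixture_params")
}

# Zero-inflated geometric number of sampled present-day descendants of one
# horizon lineage, and the coalescent-age sampler of its reconstructed
# Cenozoic subtree.
cenozoic_law <- function(params) {
  mdl <- episodic_bd_model(lambda = params$lambda_recent,
                           mu = params$mu_recent,
                           rho = params$rho_present)
  p0 <- bd_propagators(mdl, params$horizon)$p0
  e_n <- params$rho_present *
    exp((params$lambda_recent - params$mu_recent) * params$horizon)
  beta <- 1 - (1 - p0) / e_n
  list(model = mdl, p0 = p0, beta = beta)
}

# Reconstructed subtree (newick, no trailing branch) of `n` sampled tips
# descending from one horizon lineage; returns the string and its root age
# (in Myr before the present). Coalescent ages are i.i.d. with density
# ~ lambda q(u); topology is ranked-uniform.
build_cenozoic_clade <- function(label, n, params, law) {
  if (n == 1L)
    return(list(newick = label, root_age = 0))
  ages <- sort(rbranching_ages(n - 1L, law$model, params$horizon))
  items <- paste0(label, "_", seq_len(n))
  item_age <- numeric(n)
  for (u in ages) {
    pick <- sample.int(length(items), 2L)
    merged <- sprintf("(%s:%.10g,%s:%.10g)",
                      items[pick[1]], u - item_age[pick[1]],
                      items[pick[2]], u - item_age[pick[2]])
    items <- c(items[-pick], merged)
    item_age <- c(item_age[-pick], u)
  }
  list(newick = items[1], root_age = item_age[1])
}

#' Generate the synthetic study fixture
#'
#' Simulates a replicate sample of chronograms under the study truth (see
#' \code{\link{fixture_params}}), together with a binary habitat character
#' evolving with strong phylogenetic conservatism, node-age jitter emulating
#' posterior dating spread, and a truth record for parameter-recovery
#' checks.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_trees Number of replicate chronograms (default 100).
#' @param params A \code{fixture_params} object.
#' @return A list of class \code{study_fixture}: \code{trees} (multiPhylo,
#'   present-day chronograms), \code{characters} (list of named tip-state
#'   vectors), \code{horizon_counts} (true lineage counts at the horizon),
#'   \code{redraws} (per-tree rejection counts), and \code{truth} (the
#'   parameter record).
#' @export
make_study_fixture <- function(seed, n_trees = 100L,
                               params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  set.seed(seed)
  law <- cenozoic_law(params)
  span <- params$crown_age - params$horizon
  trees <- vector("list", n_trees)
  chars <- vector("list", n_trees)
  horizon_counts <- integer(n_trees)
  redraws <- integer(n_trees)
  for (i in seq_len(n_trees)) {
    accepted <- FALSE
    for (attempt in seq_len(1000L)) {
      pass <- forward_bd_pass(params$horizon_model, span)
      if (is.null(pass)) next
      surv <- pass$survivors
      n_desc <- ifelse(stats::runif(length(surv)) < law$p0, 0L,
                       1L + stats::rgeom(length(surv), 1 - law$beta))
      sampled <- surv[n_desc > 0L]
      if (length(sampled) < 2L) next
      total_tips <- sum(n_desc)
      if (total_tips < params$tip_band[1] ||
          total_tips > params$tip_band[2]) next
      # crown conditioning: both crown lineages must be represented
      anc <- function(x) {
        while (pass$parent[x] > 0L) x <- pass$parent[x]
        x
      }
      if (length(unique(vapply(sampled, anc, integer(1)))) < 2L) next
      clades <- lapply(sampled, function(id)
        build_cenozoic_clade(sprintf("t%d", id),
                             n_desc[match(id, surv)], params, law))
      names(clades) <- sprintf("t%d", sampled)
      render_tip <- function(id, top_age) {
        cl <- clades[[sprintf("t%d", id)]]
        sprintf("%s:%.10g", cl$newick,
                top_age + params$horizon - cl$root_age)
      }
      nwk <- reconstruct_newick(pass, sampled, tip_render = render_tip)
      tree <- ape::read.tree(text = nwk)
      if (params$age_jitter > 0)
        tree <- jitter_node_ages(tree, params$age_jitter)
      trees[[i]] <- tree
      chars[[i]] <- simulate_character(tree, params$q_char,
                                       params$root_state)
      horizon_counts[i] <- length(surv)
      redraws[i] <- attempt - 1L
      accepted <- TRUE
      break
    }
    if (!accepted)
      stop("fixture tree ", i, " not accepted within the redraw budget")
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, characters = chars,
                 horizon_counts = horizon_counts, redraws = redraws,
                 truth = c(params[setdiff(names(params), "horizon_model")],
                           list(seed = seed, n_trees = n_trees))),
            class = "study_fixture")
}

#' Write a fixture to disk (newick, TSV characters, JSON truth)
#'
#' @param fixture A \code{study_fixture} or \code{sim_bundle}.
#' @param dir Output directory (created if needed).
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(fixture$trees, file.path(dir, "trees.nwk"))
  hdr <- sprintf("generated with seed %s", fixture$truth$seed)
  for (i in seq_along(fixture$characters))
    write_character_table(fixture$characters[[i]],
                          file.path(dir, sprintf("characters_%03d.tsv", i)),
                          header = hdr)
  truth <- fixture$truth
  truth$tip_band <- as.numeric(truth$tip_band)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
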