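#' Run configuration for the full diversification analysis chain
#'
#' @param trees Input trees: a file path (newick/NEXUS) or a
#'   \code{multiPhylo}/list of \code{phylo}.
#' @param t_cut Analysis horizon (Myr before present; default 50). Branching
#'   times are truncated there and the horizon becomes the analysis present.
#' @param max_shifts Maximum number of rate shifts fitted (default 4).
#' @param grid_step Shift-time grid step in Myr (default 1). The grid spans
#'   the truncated data: from one step above the re-based present to the
#'   crown age.
#' @param rho Sampling fraction at the analysis present. Either an explicit
#'   value, or \code{NULL} to derive it from \code{n_present},
#'   \code{epsilon} and the tree (method-of-moments rate, diversity
#'   back-projection, lineages-in-tree; the conservative rounded value is
#'   used).
#' @param n_present Present-day standing richness used when deriving
#'   \code{rho} (default 20000).
#' @param epsilon Relative extinction rates for the rho derivation
#'   (default \code{c(0, 0.5, 0.9)}).
#' @param mom_variant Method-of-moments variant for the rho derivation.
#' @param allow_negative_r Allow negative net diversification (default
#'   TRUE).
#' @param conditioning Likelihood conditioning (\code{"crown"} or
#'   \code{"crown_n"}).
#' @param alpha Significance level of the sequential LRT (default 0.05).
#' @param posterior_sample Number of trees beyond the first to include in
#'   the posterior summary (default: all); the headline fit always uses the
#'   first tree.
#' @param characters Optional character data for ancestral state
#'   reconstruction: a file path (TSV with taxon/state columns) or a named
#'   state vector. \code{NULL} skips the ASR stage.
#' @param asr_tree Tree used for the ASR stage: \code{"first"} (default,
#'   the first input tree) or a \code{phylo}.
#' @param ltt_grid_n Number of ages in the LTT evaluation grid.
#' @param n_starts Optimizer restarts for the final refinement.
#' @param seed Integer seed governing optimizer restarts.
#' @param output_dir Directory for report files; \code{NULL} disables
#'   writing.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(trees, t_cut = 50, max_shifts = 4L, grid_step = 1,
                       rho = NULL, n_present = 20000,
                       epsilon = c(0, 0.5, 0.9), mom_variant = "crown",
                       allow_negative_r = TRUE, conditioning = "crown",
                       alpha = 0.05, posterior_sample = NULL,
                       characters = NULL, asr_tree = "first",
                       ltt_grid_n = 201L, n_starts = 5L, seed = 1L,
                       output_dir = NULL) {
  structure(list(trees = trees, t_cut = t_cut,
                 max_shifts = as.integer(max_shifts), grid_step = grid_step,
                 rho = rho, n_present = n_present, epsilon = epsilon,
                 mom_variant = mom_variant,
                 allow_negative_r = allow_negative_r,
                 conditioning = conditioning, alpha = alpha,
                 posterior_sample = posterior_sample,
                 characters = characters, asr_tree = asr_tree,
                 ltt_grid_n = as.integer(ltt_grid_n),
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full diversification analysis chain
#'
#' Stages, in order: read and validate the chronograms; LTT curves and their
#' pointwise median; truncation of branching times at the horizon;
#' derivation of the sampling fraction (when not explicit); episodic
#' birth-death fits with 0..\code{max_shifts} shifts on the first tree;
#' sequential LRT/AICc model comparison; decomposition of the selected
#' model's rates with fold-change summary; replication of fitting and
#' selection over the whole tree sample; optional ancestral state
#' reconstruction. Any stage failure aborts with the stage name. Results
#' are returned as one report list and, when \code{output_dir} is set,
#' written as TSV tables plus a combined JSON.
#'
#' @param config A \code{run_config}.
#' @return A list of class \code{pipeline_report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  trees <- stage("read_trees", {
    tr <- config$trees
    if (is.character(tr)) tr <- read_trees(tr)
    if (inherits(tr, "phylo")) tr <- list(tr)
    if (length(tr) < 1) stop("no input trees")
    lapply(tr, function(t) {
      chk <- check_ultrametric(t, tol = 1e-4)
      if (!chk$pass)
        stop("input tree not ultrametric (relative deviation ",
             format(chk$relative_deviation, digits = 3), ")")
      extend_tips_ultrametric(t)
    })
  })

  bts <- stage("branching_times", lapply(trees, branching_times))
  crown0 <- bts[[1]]$times[1]

  ltt <- stage("ltt", {
    curves <- lapply(bts, ltt_curve)
    grid_ages <- seq(0, max(vapply(bts, function(b) b$times[1], 0)),
                     length.out = config$ltt_grid_n)
    list(first = curves[[1]],
         median = median_ltt(curves, grid_ages))
  })

  bts_cut <- stage("truncate", {
    if (config$t_cut > 0) lapply(bts, truncate_at, t_cut = config$t_cut)
    else bts
  })

  rho_derivation <- NULL
  rho <- config$rho
  if (is.null(rho)) {
    rho_derivation <- stage("derive_rho", {
      derive_sampling_fraction(
        n_present = config$n_present, crown_age = crown0,
        horizon = config$t_cut, k_lineages = bts_cut[[1]]$n,
        epsilon = config$epsilon, variant = config$mom_variant)
    })
    rho <- rho_derivation$rho_conservative
  }

  crown_cut <- bts_cut[[1]]$times[1]
  grid <- list(start = config$grid_step, end = crown_cut - config$grid_step,
               step = config$grid_step)

  fits <- stage("fit_shifts", {
    out <- vector("list", config$max_shifts + 1L)
    for (m in 0:config$max_shifts) {
      out[[m + 1L]] <- fit_episodic(
        bts_cut[[1]], m, grid = grid, rho = rho,
        allow_negative_r = config$allow_negative_r,
        conditioning = config$conditioning, n_starts = config$n_starts,
        prev = if (m > 0) out[[m]] else NULL)
    }
    out
  })

  comparison <- stage("compare_models",
                      compare_models(fits, alpha = config$alpha))
  selected_m <- attr(comparison, "selected_m")
  selected <- fits[[selected_m + 1L]]

  rates_table <- stage("decompose_rates", {
    mod <- selected$model
    rt <- compose_rates(mod$lambda, mod$mu)
    bounds <- c(0, mod$shift_times, crown_cut)
    tab <- data.frame(
      interval = seq_len(mod$m + 1L),
      age_start = bounds[-length(bounds)] + config$t_cut,
      age_end = bounds[-1] + config$t_cut,
      r = rt$r, tau = rt$tau, lambda = rt$lambda, mu = rt$mu)
    if (mod$m > 0) {
      tab$fold_lambda_vs_next <- c(tab$lambda[-nrow(tab)] /
                                     tab$lambda[-1], NA)
      tab$fold_mu_vs_next <- c(tab$mu[-nrow(tab)] / tab$mu[-1], NA)
    }
    tab
  })

  posterior <- NULL
  if (length(bts_cut) >= 2) {
    sample_bts <- bts_cut
    if (!is.null(config$posterior_sample))
      sample_bts <- bts_cut[seq_len(min(length(bts_cut),
                                        config$posterior_sample))]
    posterior <- stage("posterior_summary", posterior_fit_summary(
      sample_bts, max_shifts = config$max_shifts, grid = grid, rho = rho,
      allow_negative_r = config$allow_negative_r,
      conditioning = config$conditioning, alpha = config$alpha,
      n_starts = max(1L, config$n_starts %/% 2L)))
  }

  asr <- NULL
  if (!is.null(config$characters)) {
    asr <- stage("asr", {
      states <- config$characters
      if (is.character(states) && length(states) == 1L && is.null(names(states)))
        states <- read_character_table(states)
      asr_tree <- if (identical(config$asr_tree, "first")) trees[[1]]
                  else config$asr_tree
      mk <- fit_mk(asr_tree, states)
      list(fit = mk, table = marginal_asr(asr_tree, states, mk$q))
    })
  }

  report <- structure(list(
    n_trees = length(trees), crown_age = crown0, t_cut = config$t_cut,
    rho = rho, rho_derivation = rho_derivation, ltt = ltt,
    model_table = comparison, fits = fits, selected_m = selected_m,
    rates_table = rates_table, posterior = posterior, asr = asr,
    config = config, seed = config$seed,
    package_version = as.character(utils::packageVersion("divshift"))),
    class = "pipeline_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Diversification analysis: %d tree(s), crown %.4g Ma, horizon %.4g Ma, rho = %.4g\n",
              x$n_trees, x$crown_age, x$t_cut, x$rho))
  cat(sprintf("Selected model: %d shift(s) (alpha = %g)\n", x$selected_m,
              attr(x$model_table, "alpha")))
  print(as.data.frame(x$model_table), digits = 6)
  cat("Rates through time (ages in Myr before the calendar present):\n")
  print(x$rates_table, digits = 4)
  invisible(x)
}

# TSV tables + combined JSON. Numeric output at full precision; rounding to
# the paper-style presentation (3 decimals on rates, 1 on fold changes)
# happens only here, in dedicated *_printed columns.
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(as.data.frame(report$model_table), "model_comparison.tsv")
  rt <- report$rates_table
  rt$r_printed <- round(rt$r, 3)
  rt$tau_printed <- round(rt$tau, 3)
  rt$lambda_printed <- round(rt$lambda, 3)
  rt$mu_printed <- round(rt$mu, 3)
  tsv(rt, "rates_through_time.tsv")
  if (!is.null(report$rho_derivation))
    tsv(report$rho_derivation$table, "rho_derivation.tsv")
  write_ltt(report$ltt$median, file.path(dir, "ltt_median.tsv"))
  write_ltt(report$ltt$first, file.path(dir, "ltt_first_tree.tsv"))
  if (!is.null(report$posterior))
    tsv(report$posterior$summary, "posterior_summary.tsv")
  if (!is.null(report$asr))
    tsv(as.data.frame(report$asr$table), "asr.tsv")
  json <- list(
    seed = report$seed, package_version = report$package_version,
    n_trees = report$n_trees, crown_age = report$crown_age,
    t_cut = report$t_cut, rho = report$rho,
    selected_m = report$selected_m,
    model_table = as.data.frame(report$model_table),
    rates_table = report$rates_table,
    rho_derivation = if (!is.null(report$rho_derivation))
      report$rho_derivation$table,
    posterior_summary = if (!is.null(report$posterior))
      report$posterior$summary,
    asr = if (!is.null(report$asr))
      list(q = report$asr$fit$q, loglik = report$asr$fit$loglik,
           table = as.data.frame(report$asr$table)))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
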