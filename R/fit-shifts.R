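# Maximum-likelihood fitting of episodic birth-death models with a grid
# search over shift times. Optimization is on (log lambda_i, .) transforms so
# the turnover singularity tau = 1 never enters the optimizer; results are
# reported in both (lambda, mu) and (r, tau).

# Transform between optimizer coordinates and rates.
# allow_negative_r: mu_i = exp(b_i), unconstrained relative to lambda
# otherwise:        mu_i = lambda_i * plogis(b_i)  (forces r_i >= 0)
theta_to_rates <- function(theta, n_int, allow_negative_r) {
  lambda <- exp(theta[seq_len(n_int)])
  b <- theta[n_int + seq_len(n_int)]
  mu <- if (allow_negative_r) exp(b) else lambda * stats::plogis(b)
  list(lambda = lambda, mu = mu)
}

rates_to_theta <- function(lambda, mu, allow_negative_r) {
  mu <- pmax(mu, 1e-9)
  b <- if (allow_negative_r) log(mu) else stats::qlogis(pmin(mu / lambda, 1 - 1e-9))
  c(log(lambda), b)
}

theta_bounds <- function(n_int, allow_negative_r) {
  list(lower = c(rep(log(1e-7), n_int),
                 rep(if (allow_negative_r) log(1e-10) else -30, n_int)),
       upper = c(rep(log(50), n_int),
                 rep(if (allow_negative_r) log(50) else 30, n_int)))
}

neg_loglik_fn <- function(bt, shift_times, rho, allow_negative_r,
                          conditioning) {
  n_int <- length(shift_times) + 1L
  iv <- findInterval(bt$times, shift_times, left.open = FALSE) + 1L
  times <- bt$times
  n <- bt$n
  function(theta) {
    rates <- theta_to_rates(theta, n_int, allow_negative_r)
    ll <- eloglik_core(times, n, shift_times, rates$lambda, rates$mu, rho,
                       iv, conditioning)
    if (!is.finite(ll)) 1e10 else -ll
  }
}

# One bounded quasi-Newton run with fallback to Nelder-Mead on failure.
# factr ~ 1e2 puts the stopping rule near 1e-8 absolute on logL values of
# typical magnitude; the grid scan uses a looser factor for speed and the
# selected candidate is re-polished tightly.
run_optim <- function(fn, start, bounds, factr = 1e2) {
  fit <- tryCatch(
    stats::optim(start, fn, method = "L-BFGS-B", lower = bounds$lower,
                 upper = bounds$upper,
                 control = list(factr = factr, maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- stats::optim(start, fn, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
  fit
}

# Optimize interval rates for fixed shift times; multiple starts.
optimize_rates <- function(bt, shift_times, rho, allow_negative_r,
                           conditioning, starts, factr = 1e2) {
  n_int <- length(shift_times) + 1L
  fn <- neg_loglik_fn(bt, shift_times, rho, allow_negative_r, conditioning)
  bounds <- theta_bounds(n_int, allow_negative_r)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, bounds$lower), bounds$upper)
    fit <- run_optim(fn, s, bounds, factr = factr)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$rates <- theta_to_rates(best$par, n_int, allow_negative_r)
  best
}

default_starts <- function(bt, n_int, allow_negative_r, n_starts, crown) {
  # heuristic start: pure-birth rate ln(n/2)/crown age, turnover 1/2
  lam0 <- log(max(log(max(bt$n / 2, 2)) / crown, 1e-4))
  base <- c(rep(lam0, n_int),
            rep(if (allow_negative_r) lam0 - log(2) else 0, n_int))
  starts <- list(base)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1L))
      starts[[k + 1L]] <- base + stats::rnorm(2 * n_int, 0, 1)
  }
  starts
}

#' Fit an episodic birth-death model with a grid search over shift times
#'
#' Maximum-likelihood fit of an \code{m}-shift episodic birth-death model to
#' branching times under incomplete sampling. Going backward in time, shifts
#' are added greedily: the \code{(m-1)}-shift solution's shift times are kept,
#' every grid age is scanned as the candidate for the new shift with all
#' interval rates re-optimized, the best candidate is kept, and finally all
#' rates are jointly refined with multiple random restarts (shift times stay
#' at their grid values).
#'
#' @param bt A \code{branching_times} object (possibly truncated/re-based;
#'   ages in the re-based coordinate system).
#' @param m Number of shifts (\code{>= 0}).
#' @param grid List with \code{start}, \code{end}, \code{step} (Myr; default
#'   step 1): candidate shift ages, in the same re-based coordinates as
#'   \code{bt}. Defaults to \code{step} .. just below the crown age.
#' @param rho Sampling fraction at the analysis present.
#' @param allow_negative_r Allow negative net diversification (the default,
#'   i.e. extinction may exceed speciation in any interval).
#' @param conditioning Passed to \code{\link{episodic_loglik}}.
#' @param n_starts Random restarts for the final joint refinement (default
#'   5); the grid scan itself uses a warm start from the parent model plus
#'   one heuristic start.
#' @param prev The \code{(m-1)}-shift fit to seed the greedy search
#'   (computed internally when missing).
#' @return An object of class \code{bd_shift_fit}: the fitted
#'   \code{episodic_bd} model, \code{neg_loglik}, parameter count
#'   \code{k = 2 + 3m}, \code{aicc} (small-sample size = number of branching
#'   times), and bookkeeping fields.
#' @export
fit_episodic <- function(bt, m, grid = NULL, rho = 1,
                         allow_negative_r = TRUE,
                         conditioning = c("crown", "crown_n"),
                         n_starts = 5L, prev = NULL) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(bt, "branching_times"), m >= 0)
  n_obs <- length(bt$times)
  k <- 2L + 3L * m
  if (k + 2L > n_obs)
    stop("m = ", m, " shifts need k + 2 = ", k + 2L,
         " observations but only ", n_obs, " branching times are available")
  crown <- bt$times[1]
  if (is.null(grid)) grid <- list(start = 1, end = crown - 1, step = 1)
  if (is.null(grid$step)) grid$step <- 1
  grid_ages <- seq(max(grid$start, grid$step), min(grid$end, crown - 1e-8),
                   by = grid$step)
  grid_ages <- grid_ages[grid_ages > 0 & grid_ages < crown]

  if (m == 0L) {
    sol <- optimize_rates(bt, numeric(0), rho, allow_negative_r, conditioning,
                          default_starts(bt, 1L, allow_negative_r, n_starts,
                                         crown))
    shift_times <- numeric(0)
  } else {
    if (is.null(prev))
      prev <- fit_episodic(bt, m - 1L, grid = grid, rho = rho,
                           allow_negative_r = allow_negative_r,
                           conditioning = conditioning, n_starts = n_starts)
    prev_shifts <- prev$model$shift_times
    cand <- setdiff(grid_ages, prev_shifts)
    if (length(cand) == 0) stop("no free grid ages left for shift ", m)
    best <- NULL
    best_shifts <- NULL
    for (s in cand) {
      shifts <- sort(c(prev_shifts, s))
      # warm start: parent rates with the split interval duplicated
      iv <- findInterval(s, prev_shifts) + 1L
      lam_w <- append(prev$model$lambda, prev$model$lambda[iv], after = iv)
      mu_w <- append(prev$model$mu, prev$model$mu[iv], after = iv)
      starts <- list(rates_to_theta(lam_w, mu_w, allow_negative_r))
      sol_s <- optimize_rates(bt, shifts, rho, allow_negative_r, conditioning,
                              starts, factr = 1e7)
      if (is.null(best) || sol_s$value < best$value) {
        best <- sol_s
        best_shifts <- shifts
      }
    }
    # joint refinement of all rates at the selected grid shift times
    starts <- c(list(best$par),
                default_starts(bt, m + 1L, allow_negative_r, n_starts, crown))
    sol <- optimize_rates(bt, best_shifts, rho, allow_negative_r,
                          conditioning, starts)
    shift_times <- best_shifts
  }
  model <- episodic_bd_model(shift_times = shift_times,
                             lambda = sol$rates$lambda, mu = sol$rates$mu,
                             rho = rho)
  new_bd_shift_fit(model, neg_loglik = sol$value, m = m, n_obs = n_obs,
                   t_cut = bt$t_cut, conditioning = conditioning,
                   convergence = sol$convergence == 0,
                   allow_negative_r = allow_negative_r)
}

new_bd_shift_fit <- function(model, neg_loglik, m, n_obs, t_cut = 0,
                             conditioning = "crown", convergence = TRUE,
                             allow_negative_r = TRUE) {
  k <- 2L + 3L * m
  structure(list(model = model, m = m, neg_loglik = neg_loglik, k = k,
                 aicc = aicc(neg_loglik, k, n_obs), n_obs = n_obs,
                 t_cut = t_cut, rho = model$rho, conditioning = conditioning,
                 convergence = convergence,
                 allow_negative_r = allow_negative_r),
            class = "bd_shift_fit")
}

#' Corrected Akaike information criterion
#'
#' \code{AICc = 2k + 2(-logL) + 2k(k+1)/(n_obs - k - 1)}, with the
#' small-sample size taken as the number of branching times in the analyzed
#' data. Returns \code{Inf} when the correction term's denominator is not
#' positive.
#'
#' @param neg_loglik Negative log-likelihood.
#' @param k Number of free parameters.
#' @param n_obs Number of observations (branching times).
#' @export
aicc <- function(neg_loglik, k, n_obs) {
  if (n_obs - k - 1 <= 0) return(Inf)
  2 * k + 2 * neg_loglik + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' @export
print.bd_shift_fit <- function(x, ...) {
  cat(sprintf("Episodic BD fit: m = %d shift(s), -logL = %.4f, AICc = %.4f (k = %d, n = %d)\n",
              x$m, x$neg_loglik, x$aicc, x$k, x$n_obs))
  if (!x$convergence) cat("  WARNING: optimizer did not report convergence\n")
  print(x$model)
  invisible(x)
}

#' Construct a fit summary from externally obtained values
#'
#' Builds a \code{bd_shift_fit} shell from a model dimension and a negative
#' log-likelihood, for feeding published model tables through
#' \code{\link{compare_models}} without refitting.
#'
#' @param m Number of shifts.
#' @param neg_loglik Negative log-likelihood.
#' @param n_obs Number of branching times the value refers to.
#' @export
fit_result <- function(m, neg_loglik, n_obs) {
  model <- episodic_bd_model(shift_times = if (m > 0) seq_len(m) else numeric(0),
                             lambda = rep(0.1, m + 1), mu = rep(0, m + 1),
                             rho = 1)
  new_bd_shift_fit(model, neg_loglik = neg_loglik, m = m, n_obs = n_obs)
}

#' Sequential likelihood-ratio and AICc model comparison
#'
#' Compares nested episodic birth-death fits with increasing numbers of
#' shifts. Each candidate is tested against the last \emph{accepted} model:
#' the statistic is \code{2 (logL_candidate - logL_accepted)} on
#' \code{3 (m_candidate - m_accepted)} degrees of freedom (two rates plus one
#' shift time per added shift), with the p-value from the chi-squared upper
#' tail; the candidate becomes the accepted model when \code{p < alpha}.
#' AICc is reported for every model and the minimum-AICc model is flagged
#' separately.
#'
#' @param fits List of \code{bd_shift_fit} objects ordered by increasing
#'   \code{m} on the same data.
#' @param alpha Significance level for sequential acceptance (default 0.05).
#' @return A data frame of class \code{bd_model_comparison} with one row per
#'   model: \code{m}, \code{k}, \code{neg_loglik}, \code{aicc},
#'   \code{lrt_stat}, \code{df}, \code{p_value}, \code{accepted},
#'   \code{best_aicc}. Attribute \code{selected_m} gives the LRT-selected
#'   shift count.
#' @export
compare_models <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "bd_shift_fit")))
  m <- vapply(fits, `[[`, numeric(1), "m")
  if (is.unsorted(m, strictly = TRUE))
    stop("fits must be ordered by strictly increasing shift count")
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1)
    stop("fits refer to different data (unequal numbers of branching times)")
  nll <- vapply(fits, `[[`, numeric(1), "neg_loglik")
  k <- vapply(fits, `[[`, numeric(1), "k")
  aic <- vapply(fits, `[[`, numeric(1), "aicc")
  lrt <- df <- p <- rep(NA_real_, length(fits))
  accepted <- logical(length(fits))
  accepted[1] <- TRUE
  acc <- 1L
  if (length(fits) > 1) {
    for (i in 2:length(fits)) {
      lrt[i] <- 2 * (nll[acc] - nll[i])
      df[i] <- 3 * (m[i] - m[acc])
      p[i] <- stats::pchisq(max(lrt[i], 0), df[i], lower.tail = FALSE)
      if (p[i] < alpha) {
        accepted[i] <- TRUE
        acc <- i
      }
    }
  }
  out <- data.frame(m = m, k = k, neg_loglik = nll, aicc = aic,
                    lrt_stat = lrt, df = df, p_value = p,
                    accepted = accepted, best_aicc = aic == min(aic))
  attr(out, "selected_m") <- m[acc]
  attr(out, "alpha") <- alpha
  class(out) <- c("bd_model_comparison", "data.frame")
  out
}

#' Repeat shift fitting and model selection over a sample of trees
#'
#' Runs \code{\link{fit_episodic}} for \code{m = 0..max_shifts} and
#' \code{\link{compare_models}} on each tree of a (posterior) sample, then
#' aggregates the parameters of the selected model across the trees whose
#' selected shift count equals the modal selected count: means, standard
#' errors, and 2.5/97.5 percentiles per parameter. Per-tree failures are
#' caught, counted and excluded.
#'
#' @param bt_list List of \code{branching_times} objects.
#' @param max_shifts Maximum shift count fitted per tree.
#' @param grid,rho,allow_negative_r,conditioning,n_starts Passed to
#'   \code{\link{fit_episodic}}.
#' @param alpha Passed to \code{\link{compare_models}}.
#' @return A list of class \code{posterior_fit_summary}: \code{n_trees},
#'   \code{n_failed}, \code{selected_m} (per-tree vector), \code{modal_m},
#'   \code{params} (per-tree matrix for trees at the modal m), and
#'   \code{summary} (data frame with mean, se, and percentile columns).
#' @export
posterior_fit_summary <- function(bt_list, max_shifts = 1L, grid = NULL,
                                  rho = 1, allow_negative_r = TRUE,
                                  conditioning = "crown", n_starts = 3L,
                                  alpha = 0.05) {
  stopifnot(length(bt_list) >= 2)
  selected <- integer(0)
  rows <- list()
  failures <- 0L
  for (i in seq_along(bt_list)) {
    res <- tryCatch({
      fits <- vector("list", max_shifts + 1L)
      for (mm in 0:max_shifts)
        fits[[mm + 1L]] <- fit_episodic(
          bt_list[[i]], mm, grid = grid, rho = rho,
          allow_negative_r = allow_negative_r, conditioning = conditioning,
          n_starts = n_starts,
          prev = if (mm > 0) fits[[mm]] else NULL)
      cmp <- compare_models(fits, alpha = alpha)
      sel <- attr(cmp, "selected_m")
      list(sel = sel, fit = fits[[sel + 1L]])
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      next
    }
    selected <- c(selected, res$sel)
    rows[[length(rows) + 1L]] <- res$fit
  }
  if (length(rows) == 0) stop("all per-tree fits failed")
  tab <- table(selected)
  modal_m <- as.integer(names(tab)[which.max(tab)])
  keep <- vapply(rows, function(f) f$m == modal_m, TRUE)
  par_mat <- do.call(rbind, lapply(rows[keep], fit_param_vector))
  qs <- apply(par_mat, 2, stats::quantile, probs = c(0.025, 0.975))
  summary_df <- data.frame(
    parameter = colnames(par_mat),
    mean = colMeans(par_mat),
    se = apply(par_mat, 2, stats::sd) / sqrt(nrow(par_mat)),
    q2.5 = qs[1, ], q97.5 = qs[2, ], row.names = NULL)
  structure(list(n_trees = length(bt_list), n_failed = failures,
                 selected_m = selected, modal_m = modal_m,
                 n_aggregated = nrow(par_mat), params = par_mat,
                 summary = summary_df),
            class = "posterior_fit_summary")
}

# Flatten a fit's parameters into a named vector (youngest interval first).
fit_param_vector <- function(fit) {
  mod <- fit$model
  rt <- compose_rates(mod$lambda, mod$mu)
  n_int <- mod$m + 1L
  v <- c(rt$r, rt$tau, mod$lambda, mod$mu, mod$shift_times, fit$neg_loglik)
  names(v) <- c(paste0("r", seq_len(n_int)), paste0("tau", seq_len(n_int)),
                paste0("lambda", seq_len(n_int)), paste0("mu", seq_len(n_int)),
                if (mod$m > 0) paste0("shift_time", seq_len(mod$m)),
                "neg_loglik")
  v
}

#' @export
print.posterior_fit_summary <- function(x, ...) {
  cat(sprintf("Posterior fit summary over %d trees (%d failed):\n",
              x$n_trees, x$n_failed))
  cat("  selected shift counts:",
      paste(names(table(x$selected_m)), table(x$selected_m),
            sep = "x", collapse = ", "), "\n")
  cat(sprintf("  aggregating %d trees at modal m = %d\n", x$n_aggregated,
              x$modal_m))
  print(x$summary, digits = 4)
  invisible(x)
}
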