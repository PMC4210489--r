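# Birth-death propagators on the age axis.
#
# p0(u): probability that a single lineage alive at age u leaves no sampled
#        descendant at the analysis present; p0(0) = 1 - rho.
# q(u):  reconstructed-lineage propagator (probability of exactly one sampled
#        descendant, with the reconstructed-tree density interpretation);
#        q(0) = rho.
#
# Within an interval with constant rates (lambda, mu), entry value p~ at the
# interval's young end and relative age x:
#   p0(u) = 1 - (1-p~)(lambda-mu) /
#               ((1-p~)lambda + (lambda*p~ - mu) e^{-(lambda-mu)x})
#   q(u)  = q(entry) (lambda-mu)^2 e^{-(lambda-mu)x} /
#               ((1-p~)lambda + (lambda*p~ - mu) e^{-(lambda-mu)x})^2
# In the critical case |lambda - mu| < crit_tol the exponential forms are
# replaced by their lambda = mu limits, rational in lambda*x:
#   p0(u) = 1 - (1-p~) / (1 + (1-p~) lambda x)
#   q(u)  = q(entry) / (1 + (1-p~) lambda x)^2
# At a shift boundary with survival probability rho_i (mass extinction),
#   p0 -> (1 - rho_i) + rho_i p0,  q -> rho_i q  (identity at rho_i = 1).
#
# q is tracked on the log scale; p0 stays in [0, 1] throughout.

.crit_tol <- 1e-8

# Boundary values of (p0, log q) at the young end of every interval.
# Returns matrices over intervals 1..m+1: entry_p0, entry_logq, plus the
# interval start ages.
propagator_boundaries <- function(model) {
  m <- model$m
  starts <- c(0, model$shift_times)
  p0 <- numeric(m + 1L)
  logq <- numeric(m + 1L)
  p0[1] <- 1 - model$rho
  logq[1] <- log(model$rho)
  if (m > 0) {
    for (i in seq_len(m)) {
      seg <- propagate_interval(p0[i], logq[i],
                                model$lambda[i], model$mu[i],
                                model$shift_times[i] - starts[i])
      # mass-extinction mapping at the shift (identity when boundary_rho = 1)
      srv <- model$boundary_rho[i]
      p0[i + 1L] <- (1 - srv) + srv * seg$p0
      logq[i + 1L] <- seg$logq + log(srv)
    }
  }
  list(starts = starts, p0 = p0, logq = logq)
}

# Advance (p0, log q) by relative age x under constant rates; vectorized in x.
propagate_interval <- function(p0_in, logq_in, lambda, mu, x) {
  a <- 1 - p0_in
  if (abs(lambda - mu) < .crit_tol) {
    denom <- 1 + a * lambda * x
    list(p0 = 1 - a / denom, logq = logq_in - 2 * log(denom))
  } else {
    # the denominator carries the sign of (lambda - mu): for declining
    # diversity both are negative and the ratios stay positive
    d <- lambda - mu
    e <- exp(-d * x)
    denom <- a * lambda + (lambda * p0_in - mu) * e
    list(p0 = 1 - a * d / denom,
         logq = logq_in + 2 * log(abs(d)) - d * x - 2 * log(abs(denom)))
  }
}

# Lean likelihood kernel used inside optimization loops: no S3 objects, no
# data frames. `iv` is the precomputed interval index of each branching time
# (findInterval(times, shift_times) + 1), constant while rates vary.
# Returns -Inf for inadmissible rate combinations (non-positive propagator
# denominators) instead of erroring.
eloglik_core <- function(times, n, shift_times, lambda, mu, rho, iv,
                         conditioning = "crown") {
  m <- length(shift_times)
  starts <- c(0, shift_times)
  p0_b <- 1 - rho
  logq_b <- log(rho)
  p0 <- numeric(length(times))
  logq <- numeric(length(times))
  for (j in seq_len(m + 1L)) {
    a <- 1 - p0_b
    lam <- lambda[j]
    muj <- mu[j]
    sel <- iv == j
    if (any(sel)) {
      x <- times[sel] - starts[j]
      if (abs(lam - muj) < .crit_tol) {
        denom <- 1 + a * lam * x
        p0[sel] <- 1 - a / denom
        logq[sel] <- logq_b - 2 * log(denom)
      } else {
        d <- lam - muj
        denom <- a * lam + (lam * p0_b - muj) * exp(-d * x)
        if (any(d * denom <= 0)) return(-Inf)    # numerical guard
        p0[sel] <- 1 - a * d / denom
        logq[sel] <- logq_b + 2 * log(abs(d)) - d * x - 2 * log(abs(denom))
      }
    }
    if (j <= m) {
      x <- shift_times[j] - starts[j]
      if (abs(lam - muj) < .crit_tol) {
        denom <- 1 + a * lam * x
        p0_b <- 1 - a / denom
        logq_b <- logq_b - 2 * log(denom)
      } else {
        d <- lam - muj
        denom <- a * lam + (lam * p0_b - muj) * exp(-d * x)
        if (d * denom <= 0) return(-Inf)         # numerical guard
        p0_b <- 1 - a * d / denom
        logq_b <- logq_b + 2 * log(abs(d)) - d * x - 2 * log(abs(denom))
      }
    }
  }
  surv <- 1 - p0[1]
  if (surv <= 0) return(-Inf)
  ll <- 2 * logq[1] - 2 * log(surv)
  if (n > 2L) ll <- ll + sum(log(lambda[iv[-1]]) + logq[-1])
  if (conditioning == "crown_n") {
    durations <- diff(c(0, shift_times, times[1]))
    expected_n <- rho * exp(sum((lambda - mu) * durations))
    # p0 at the crown age: entry of the oldest interval advanced to times[1]
    beta <- 1 - surv / expected_n
    if (beta >= 1) return(-Inf)
    if (beta <= 0) {
      if (n > 2L) return(-Inf)          # P(n) = 0 for n > 2 at beta = 0
    } else {
      ll <- ll - (log(n - 1) + 2 * log(1 - beta) + (n - 2) * log(beta))
    }
  }
  ll
}

#' Evaluate the birth-death propagators of an episodic model
#'
#' Computes \code{p0(u)} (probability of leaving no sampled descendant) and
#' \code{log q(u)} (log of the reconstructed-lineage propagator) at arbitrary
#' ages, together with the speciation rate of the interval containing each
#' age.
#'
#' @param model An \code{episodic_bd} model.
#' @param ages Ages (Myr before the analysis present), \code{>= 0}.
#' @return A data frame with columns \code{age}, \code{interval}, \code{p0},
#'   \code{logq}, \code{lambda}.
#' @export
bd_propagators <- function(model, ages) {
  stopifnot(inherits(model, "episodic_bd"), all(ages >= 0))
  bnd <- propagator_boundaries(model)
  iv <- findInterval(ages, model$shift_times, left.open = FALSE) + 1L
  # age exactly at a shift time belongs to the older interval (left.open=FALSE
  # gives that: findInterval(t_i, t) = i -> interval i+1)
  p0 <- numeric(length(ages))
  logq <- numeric(length(ages))
  for (j in unique(iv)) {
    sel <- iv == j
    seg <- propagate_interval(bnd$p0[j], bnd$logq[j],
                              model$lambda[j], model$mu[j],
                              ages[sel] - bnd$starts[j])
    p0[sel] <- seg$p0
    logq[sel] <- seg$logq
  }
  data.frame(age = ages, interval = iv, p0 = p0, logq = logq,
             lambda = model$lambda[iv])
}

#' Log-likelihood of branching times under an episodic birth-death model
#'
#' The reconstructed-tree log-likelihood of the branching times
#' \code{x_1 > x_2 >= ... >= x_{n-1}} (crown age first) under a
#' piecewise-constant birth-death process with sampling fraction \code{rho}
#' at the analysis present, conditioned by default on the crown age and on
#' both crown lineages having sampled descendants:
#' \deqn{\log L = \sum_{i=2}^{n-1}[\log\lambda(x_i) + \log q(x_i)]
#'   + 2\log q(x_1) - 2\log(1 - p_0(x_1)).}
#' The value is a density up to a parameter-independent constant; only
#' differences between models on the same data are meaningful.
#'
#' @param bt A \code{branching_times} object.
#' @param model An \code{episodic_bd} model; shift times must lie strictly
#'   inside \code{(0, crown age)}.
#' @param conditioning \code{"crown"} (crown age + survival of both crown
#'   lineages; default) or \code{"crown_n"} (additionally conditions on the
#'   observed number of sampled lineages).
#' @return The log-likelihood (scalar).
#' @export
episodic_loglik <- function(bt, model, conditioning = c("crown", "crown_n")) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(bt, "branching_times"), inherits(model, "episodic_bd"))
  crown <- bt$times[1]
  if (model$m > 0 && any(model$shift_times >= crown))
    stop("shift times must lie strictly inside (0, crown age)")
  pr <- bd_propagators(model, bt$times)
  surv <- 1 - pr$p0[1]
  if (surv <= 0) return(-Inf)
  ll <- 2 * pr$logq[1] - 2 * log(surv)
  if (bt$n > 2L)
    ll <- ll + sum(log(pr$lambda[-1]) + pr$logq[-1])
  if (conditioning == "crown_n")
    ll <- ll - log_prob_n_given_crown(model, crown, bt$n)
  ll
}

# P(n sampled tips | crown age, both crown lineages survive): the number of
# sampled descendants of a single surviving lineage at the crown age is
# geometric, so n = N1 + N2 has a negative-binomial-type form
# (n-1)(1-beta)^2 beta^(n-2) with beta = 1 - (1 - p0(T)) / E[N].
log_prob_n_given_crown <- function(model, crown, n) {
  pr <- bd_propagators(model, crown)
  durations <- diff(c(0, model$shift_times, crown))
  r <- model$lambda - model$mu
  expected_n <- model$rho * exp(sum(r * durations)) * prod(model$boundary_rho)
  beta <- 1 - (1 - pr$p0) / expected_n
  if (beta >= 1) return(-Inf)
  if (beta <= 0) return(if (n == 2L) 0 else -Inf)
  log(n - 1) + 2 * log(1 - beta) + (n - 2) * log(beta)
}

#' Log-likelihood via numerical integration of the propagator ODEs
#'
#' An independent evaluation path for \code{\link{episodic_loglik}}: the
#' propagators are obtained by integrating
#' \deqn{dp_0/du = \mu - (\lambda+\mu)p_0 + \lambda p_0^2, \qquad
#'   d\log q/du = -(\lambda+\mu) + 2\lambda p_0}
#' piecewise over the model's intervals with an adaptive solver, instead of
#' the closed forms. Used as an internal cross-check; the closed form is the
#' production path.
#'
#' @inheritParams episodic_loglik
#' @param rtol,atol Solver tolerances.
#' @return The log-likelihood (scalar).
#' @export
episodic_loglik_ode <- function(bt, model, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(bt, "branching_times"), inherits(model, "episodic_bd"))
  crown <- bt$times[1]
  if (model$m > 0 && any(model$shift_times >= crown))
    stop("shift times must lie strictly inside (0, crown age)")
  ages <- sort(unique(bt$times))
  bounds <- c(0, model$shift_times[model$shift_times < max(ages)], max(ages))
  state <- c(p0 = 1 - model$rho, logq = log(model$rho))
  p0_at <- numeric(length(ages))
  logq_at <- numeric(length(ages))
  deriv <- function(u, y, parms) {
    list(c(parms$mu - (parms$lambda + parms$mu) * y[1] +
             parms$lambda * y[1]^2,
           -(parms$lambda + parms$mu) + 2 * parms$lambda * y[1]))
  }
  for (j in seq_len(length(bounds) - 1L)) {
    lo <- bounds[j]; hi <- bounds[j + 1L]
    iv <- findInterval(lo, model$shift_times, left.open = FALSE) + 1L
    inside <- ages[ages > lo & ages <= hi]
    times <- sort(unique(c(lo, inside, hi)))
    sol <- deSolve::lsoda(state, times, deriv,
                          parms = list(lambda = model$lambda[iv],
                                       mu = model$mu[iv]),
                          rtol = rtol, atol = atol)
    idx <- match(inside, sol[, "time"])
    p0_at[match(inside, ages)] <- sol[idx, "p0"]
    logq_at[match(inside, ages)] <- sol[idx, "logq"]
    state <- c(p0 = unname(sol[nrow(sol), "p0"]),
               logq = unname(sol[nrow(sol), "logq"]))
    if (hi %in% model$shift_times) {
      srv <- model$boundary_rho[match(hi, model$shift_times)]
      state["p0"] <- (1 - srv) + srv * state["p0"]
      state["logq"] <- state["logq"] + log(srv)
    }
  }
  pos <- match(bt$times, ages)
  p0 <- p0_at[pos]
  logq <- logq_at[pos]
  iv <- findInterval(bt$times, model$shift_times, left.open = FALSE) + 1L
  surv <- 1 - p0[1]
  if (surv <= 0) return(-Inf)
  ll <- 2 * logq[1] - 2 * log(surv)
  if (bt$n > 2L)
    ll <- ll + sum(log(model$lambda[iv[-1]]) + logq[-1])
  ll
}
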