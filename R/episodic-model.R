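#' Construct an episodic birth-death model
#'
#' A birth-death process with piecewise-constant speciation and extinction
#' rates separated by shift times, and a sampling fraction at the analysis
#' present. Intervals are numbered from the present: interval 1 covers ages
#' \code{[0, shift_times[1])}, interval 2 covers
#' \code{[shift_times[1], shift_times[2])}, and so on; with \code{m} shifts
#' there are \code{m + 1} intervals. Rates can be given either as
#' speciation/extinction (\code{lambda}, \code{mu}) or as net
#' diversification/turnover (\code{r}, \code{tau}); the two parameterizations
#' are related by \code{lambda = r/(1 - tau)}, \code{mu = r*tau/(1 - tau)}.
#'
#' @param shift_times Strictly increasing ages (Myr before the analysis
#'   present) of the rate shifts; \code{numeric(0)} for a constant-rate model.
#' @param lambda,mu Per-interval speciation and extinction rates (Myr^-1),
#'   youngest interval first; \code{lambda > 0}, \code{mu >= 0}.
#' @param r,tau Alternative parameterization: per-interval net
#'   diversification and turnover.
#' @param rho Sampling fraction at the analysis present, in (0, 1].
#' @param boundary_rho Per-shift survival probabilities (mass-extinction
#'   intensity at each shift time); default 1 = no mass extinction, which is
#'   the only setting exercised by the pipeline.
#' @return An object of class \code{episodic_bd}.
#' @export
episodic_bd_model <- function(shift_times = numeric(0), lambda = NULL,
                              mu = NULL, r = NULL, tau = NULL, rho = 1,
                              boundary_rho = NULL) {
  shift_times <- as.numeric(shift_times)
  if (is.unsorted(shift_times, strictly = TRUE))
    stop("shift_times must be strictly increasing ages")
  if (any(shift_times <= 0)) stop("shift times must be positive ages")
  m <- length(shift_times)
  if (is.null(lambda) != is.null(mu) || is.null(r) != is.null(tau))
    stop("supply both members of a rate pair")
  if (!is.null(lambda) && !is.null(r))
    stop("supply either (lambda, mu) or (r, tau), not both")
  if (!is.null(r)) {
    rates <- decompose_rates(r, tau)
    lambda <- rates$lambda
    mu <- rates$mu
  }
  if (is.null(lambda)) stop("no rates supplied")
  if (length(lambda) != m + 1L || length(mu) != m + 1L)
    stop("need exactly m + 1 = ", m + 1L, " rates per parameter; got ",
         length(lambda))
  if (any(lambda <= 0)) stop("speciation rates must be positive")
  if (any(mu < 0)) stop("extinction rates must be non-negative")
  if (length(rho) != 1L || rho <= 0 || rho > 1)
    stop("rho must be a single value in (0, 1]")
  if (is.null(boundary_rho)) boundary_rho <- rep(1, m)
  if (length(boundary_rho) != m || any(boundary_rho <= 0 | boundary_rho > 1))
    stop("boundary_rho must have one value in (0, 1] per shift")
  structure(list(shift_times = shift_times, lambda = as.numeric(lambda),
                 mu = as.numeric(mu), rho = rho,
                 boundary_rho = as.numeric(boundary_rho), m = m),
            class = "episodic_bd")
}

#' @export
print.episodic_bd <- function(x, ...) {
  rt <- compose_rates(x$lambda, x$mu)
  cat(sprintf("Episodic birth-death model: %d shift(s), rho = %.4g\n", x$m,
              x$rho))
  bounds <- c(0, x$shift_times)
  for (i in seq_len(x$m + 1)) {
    upper <- if (i <= x$m) sprintf("%.4g", x$shift_times[i]) else "crown"
    cat(sprintf("  interval %d [%.4g, %s) Myr: lambda=%.4g mu=%.4g r=%.4g tau=%.4g\n",
                i, bounds[i], upper, x$lambda[i], x$mu[i], rt$r[i], rt$tau[i]))
  }
  invisible(x)
}

#' Decompose net diversification and turnover into speciation and extinction
#'
#' Applies \code{lambda = r/(1 - tau)} and \code{mu = r*tau/(1 - tau)}.
#' The pair is admissible only when the implied \code{lambda} is positive and
#' \code{mu} non-negative: either \code{r > 0} with \code{tau < 1}, or
#' \code{r < 0} with \code{tau > 1} (declining diversity).
#'
#' @param r Net diversification rate(s), Myr^-1 (may be negative).
#' @param tau Turnover(s), dimensionless, \code{>= 0} and \code{!= 1}.
#' @return A data frame with columns \code{r}, \code{tau}, \code{lambda},
#'   \code{mu}.
#' @export
decompose_rates <- function(r, tau) {
  stopifnot(length(r) == length(tau))
  if (any(tau < 0)) stop("turnover must be non-negative")
  if (any(tau == 1)) stop("turnover = 1 is singular (lambda undefined)")
  lambda <- r / (1 - tau)
  mu <- r * tau / (1 - tau)
  bad <- lambda <= 0
  if (any(bad))
    stop("inadmissible (r, tau) pair(s) at position ",
         paste(which(bad), collapse = ", "),
         ": implied speciation rate would not be positive")
  data.frame(r = r, tau = tau, lambda = lambda, mu = mu)
}

#' Compose speciation and extinction into net diversification and turnover
#'
#' The inverse of \code{\link{decompose_rates}}: \code{r = lambda - mu},
#' \code{tau = mu/lambda}.
#'
#' @param lambda Speciation rate(s), \code{> 0}.
#' @param mu Extinction rate(s), \code{>= 0}.
#' @return A data frame with columns \code{lambda}, \code{mu}, \code{r},
#'   \code{tau}.
#' @export
compose_rates <- function(lambda, mu) {
  stopifnot(length(lambda) == length(mu))
  if (any(lambda <= 0)) stop("speciation rates must be positive")
  if (any(mu < 0)) stop("extinction rates must be non-negative")
  data.frame(lambda = lambda, mu = mu, r = lambda - mu, tau = mu / lambda)
}
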