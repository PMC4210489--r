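#' Method-of-moments net diversification rate
#'
#' Closed-form estimator of the net diversification rate from a clade's
#' extant species richness, age, and an assumed relative extinction
#' \code{epsilon = mu/lambda} (Magallon-Sanderson estimators). The crown
#' variant is
#' \deqn{\hat r = \frac{1}{t}\left[\log\left(\frac{N(1-\epsilon^2)}{2} +
#'   2\epsilon + \frac{1-\epsilon}{2}
#'   \sqrt{N(N\epsilon^2 - 8\epsilon + 2N\epsilon + N)}\right) -
#'   \log 2\right],}
#' which reduces to \eqn{\log(N/2)/t} at \eqn{\epsilon = 0}; the stem variant
#' is \eqn{\log(N(1-\epsilon)+\epsilon)/t}.
#'
#' @param N Extant species richness (\code{>= 2} for the crown variant).
#' @param t Clade age in Myr (crown or stem age to match \code{variant}).
#' @param epsilon Relative extinction rate in \code{[0, 1)}; may be a vector.
#' @param variant \code{"crown"} (default) or \code{"stem"}.
#' @return Net diversification rate(s) in Myr^-1.
#' @export
mom_rate <- function(N, t, epsilon = 0, variant = c("crown", "stem")) {
  variant <- match.arg(variant)
  stopifnot(N >= 2, t > 0)
  if (any(epsilon < 0 | epsilon >= 1))
    stop("epsilon must lie in [0, 1)")
  if (variant == "stem") {
    log(N * (1 - epsilon) + epsilon) / t
  } else {
    arg <- N * (1 - epsilon^2) / 2 + 2 * epsilon +
      (1 - epsilon) / 2 * sqrt(N * (N * epsilon^2 - 8 * epsilon +
                                      2 * N * epsilon + N))
    (log(arg) - log(2)) / t
  }
}

#' Back-project standing diversity to a time horizon
#'
#' Infers the number of species at a past horizon from present diversity and
#' a net diversification rate. The default \code{"ratio"} method is
#' \deqn{N_{horizon} = \frac{N_{present}}{horizon \times r},} the form used
#' to derive the analysis sampling fraction; the \code{"exponential"}
#' alternative is the decay projection
#' \eqn{N_{present} e^{-r \cdot horizon}}.
#'
#' @param n_present Present-day species richness.
#' @param horizon Horizon in Myr before present.
#' @param r Net diversification rate (Myr^-1), \code{> 0}; may be a vector.
#' @param method \code{"ratio"} (default) or \code{"exponential"}.
#' @return Projected richness at the horizon.
#' @export
project_diversity <- function(n_present, horizon, r,
                              method = c("ratio", "exponential")) {
  method <- match.arg(method)
  stopifnot(n_present > 0, horizon > 0)
  if (any(r <= 0)) stop("projection requires a positive diversification rate")
  switch(method,
         ratio = n_present / (horizon * r),
         exponential = n_present * exp(-r * horizon))
}

#' Sampling fraction at an analysis horizon
#'
#' The fraction of lineages extant at the horizon that are represented in the
#' phylogeny: the number of lineages the tree has crossing the horizon
#' divided by the projected total richness there.
#'
#' @param k_lineages Lineages in the tree at the horizon (\code{>= 1}).
#' @param n_horizon Projected total richness at the horizon; may be a vector.
#' @return Sampling fraction(s) in (0, 1].
#' @export
sampling_fraction <- function(k_lineages, n_horizon) {
  stopifnot(k_lineages >= 1)
  if (any(k_lineages > n_horizon))
    stop("more sampled lineages than projected total richness")
  k_lineages / n_horizon
}

#' Derive a sampling fraction from richness, age and relative extinction
#'
#' The full derivation chain used to set the analysis sampling fraction: for
#' each assumed relative extinction, a method-of-moments rate, the
#' back-projected richness at the horizon, and the implied sampling fraction;
#' plus a conservative value obtained by rounding the largest implied
#' fraction up to two decimals.
#'
#' @param n_present Present species richness.
#' @param crown_age Crown age (Myr) used by the method of moments.
#' @param horizon Analysis horizon (Myr).
#' @param k_lineages Lineages in the tree at the horizon.
#' @param epsilon Vector of relative extinction rates.
#' @param variant Method-of-moments variant.
#' @return A list with \code{table} (one row per epsilon: \code{epsilon},
#'   \code{r}, \code{n_horizon}, \code{rho}) and \code{rho_conservative}.
#' @export
derive_sampling_fraction <- function(n_present, crown_age, horizon,
                                     k_lineages, epsilon = c(0, 0.5, 0.9),
                                     variant = "crown") {
  r <- mom_rate(n_present, crown_age, epsilon, variant = variant)
  n_h <- project_diversity(n_present, horizon, r)
  rho <- sampling_fraction(k_lineages, n_h)
  list(table = data.frame(epsilon = epsilon, r = r, n_horizon = n_h,
                          rho = rho),
       rho_conservative = ceiling(max(rho) * 100) / 100)
}
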