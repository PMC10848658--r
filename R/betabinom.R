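#' Beta-binomial distribution in the (mu, rho) parameterization
#'
#' The beta-binomial arises by drawing a per-trial success probability
#' `pi ~ Beta(alpha, beta)` and then a count `X ~ Binomial(n, pi)`. Instead of
#' (alpha, beta) we parameterize by the mean per-token success probability
#' `mu = alpha / (alpha + beta)` and the intraclass correlation
#' `rho = 1 / (alpha + beta + 1)`, which governs overdispersion: at fixed
#' (n, mu) the variance is `n mu (1 - mu) (1 + (n - 1) rho)`. `rho = 0` is the
#' binomial limit; `rho -> 1` is all-or-nothing (U-shaped) recognition.
#'
#' @name betabinomial
NULL

#' Validated beta-binomial parameter set
#'
#' @param n tokens per trial, positive integer (scalar).
#' @param mu mean per-token success probability, in (0, 1).
#' @param rho intraclass correlation, in \[0, 1). `rho = 0` selects the
#'   binomial limit.
#' @return an object of class `bb_params` (a list with `n`, `mu`, `rho`).
#' @examples
#' bb_params(3, 0.5, 0.35)
#' @export
bb_params <- function(n, mu, rho) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n))
    stop_domain("`n` must be a positive integer, got %s", format(n))
  if (length(mu) != 1 || !is.finite(mu) || mu <= 0 || mu >= 1)
    stop_domain("`mu` must lie strictly in (0, 1), got %s", format(mu))
  if (length(rho) != 1 || !is.finite(rho) || rho < 0 || rho >= 1)
    stop_domain("`rho` must lie in [0, 1), got %s", format(rho))
  structure(list(n = as.integer(n), mu = mu, rho = rho), class = "bb_params")
}

#' Convert (mu, rho) to beta shape parameters (alpha, beta)
#'
#' Inverts `mu = alpha / (alpha + beta)` and `rho = 1 / (alpha + beta + 1)`:
#' with `s = 1 / rho - 1`, `alpha = mu * s` and `beta = (1 - mu) * s`.
#' `rho = 0` has no beta representation (the binomial limit is handled by the
#' pmf/moments/sampling functions, not by this map) and is rejected.
#'
#' @param mu mean success probability in (0, 1).
#' @param rho intraclass correlation in (0, 1), strictly positive.
#' @return list with components `alpha` and `beta`, both positive.
#' @examples
#' mu_rho_to_alpha_beta(0.5, 0.5)  # alpha = beta = 0.5
#' @export
mu_rho_to_alpha_beta <- function(mu, rho) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stop_domain("`mu` must lie strictly in (0, 1)")
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho >= 1))
    stop_domain("`rho` must lie strictly in (0, 1); rho = 0 is the binomial limit and has no (alpha, beta) representation")
  s <- 1 / rho - 1
  list(alpha = mu * s, beta = (1 - mu) * s)
}

#' Convert beta shape parameters (alpha, beta) to (mu, rho)
#'
#' @param alpha,beta positive beta shape parameters.
#' @return list with components `mu` and `rho`.
#' @export
alpha_beta_to_mu_rho <- function(alpha, beta) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop_domain("`alpha` must be positive")
  if (any(!is.finite(beta)) || any(beta <= 0))
    stop_domain("`beta` must be positive")
  list(mu = alpha / (alpha + beta), rho = 1 / (alpha + beta + 1))
}

#' Beta-binomial probability mass function
#'
#' Computed in log space as
#' `log C(n, k) + log B(k + alpha, n - k + beta) - log B(alpha, beta)`
#' via log-gamma, which stays stable for small `rho` (large `alpha + beta`).
#' `rho = 0` falls back to the binomial pmf.
#'
#' @param k count(s) of tokens correct, each in 0..n.
#' @param n tokens per trial (scalar or vector recycled with `k`).
#' @param mu mean success probability in (0, 1).
#' @param rho intraclass correlation in \[0, 1).
#' @param log return log probabilities?
#' @return vector of (log) probabilities.
#' @examples
#' dbetabinom(0:3, 3, 0.5, 0.35)
#' @export
dbetabinom <- function(k, n, mu, rho, log = FALSE) {
  if (any(!is.finite(k)) || any(k < 0) || any(k > n) || any(k != round(k)))
    stop_domain("`k` must be an integer count in 0..n")
  if (any(rho < 0) || any(rho >= 1))
    stop_domain("`rho` must lie in [0, 1)")
  # at and below rho ~ 1e-8 the lgamma formula loses precision while the
  # binomial limit is exact to ~n^2 rho < 1e-6; use the limit there
  if (all(rho <= 1e-8)) return(stats::dbinom(k, n, mu, log = log))
  ab <- mu_rho_to_alpha_beta(mu, rho)
  lp <- lchoose(n, k) + lbeta(k + ab$alpha, n - k + ab$beta) -
    lbeta(ab$alpha, ab$beta)
  if (log) lp else exp(lp)
}

#' Full count distribution over k = 0..n
#'
#' @param params a [bb_params()] object.
#' @return list of class `count_distribution` with `n` and `probs`
#'   (length `n + 1`, summing to 1).
#' @export
bb_pmf_table <- function(params) {
  stopifnot(inherits(params, "bb_params"))
  probs <- dbetabinom(0:params$n, params$n, params$mu, params$rho)
  structure(list(n = params$n, probs = probs), class = "count_distribution")
}

#' Mean and variance of the beta-binomial count
#'
#' `mean = n mu`; `variance = n mu (1 - mu) (1 + (n - 1) rho)` — the binomial
#' variance inflated by the design effect `1 + (n - 1) rho`.
#'
#' @param params a [bb_params()] object.
#' @return list with `mean` and `variance`.
#' @export
bb_moments <- function(params) {
  stopifnot(inherits(params, "bb_params"))
  n <- params$n; mu <- params$mu; rho <- params$rho
  list(mean = n * mu, variance = n * mu * (1 - mu) * (1 + (n - 1) * rho))
}

#' Sample beta-binomial counts by the two-stage compositional scheme
#'
#' For each trial a fresh `pi ~ Beta(alpha, beta)` is drawn and then
#' `X ~ Binomial(n, pi)`, mirroring the generative story (context fixes a
#' per-stimulus recognition probability; tokens are then conditionally
#' independent). At `rho = 0` sampling is directly binomial. The per-trial
#' `pi` draws are attached as attribute `"pi"` for diagnostics.
#'
#' @param n_trials number of trials to draw (>= 1).
#' @param params a [bb_params()] object.
#' @param seed optional integer; when given, sampling runs under this seed
#'   without disturbing the caller's RNG state.
#' @return integer vector of counts in 0..n with attribute `pi`.
#' @examples
#' rbetabinom(5, bb_params(3, 0.5, 0.35), seed = 1)
#' @export
rbetabinom <- function(n_trials, params, seed = NULL) {
  stopifnot(inherits(params, "bb_params"))
  if (length(n_trials) != 1 || !is.finite(n_trials) || n_trials < 1)
    stop_domain("`n_trials` must be a positive integer")
  draw <- function() {
    if (params$rho == 0) {
      pi <- rep(params$mu, n_trials)
    } else {
      ab <- mu_rho_to_alpha_beta(params$mu, params$rho)
      pi <- stats::rbeta(n_trials, ab$alpha, ab$beta)
    }
    x <- stats::rbinom(n_trials, params$n, pi)
    attr(x, "pi") <- pi
    x
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}
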