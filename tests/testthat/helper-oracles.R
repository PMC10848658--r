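# Shared fixtures and independent oracles, built in code at test time.

# beta-binomial pmf by numerical integration over the beta measure:
# P(X = k) = \int_0^1 dbinom(k, n, qbeta(u, a, b)) du
# (quantile substitution keeps the integrand bounded even when the beta
# density is endpoint-singular)
quadrature_pmf <- function(k, n, mu, rho) {
  ab <- mu_rho_to_alpha_beta(mu, rho)
  vapply(k, function(ki)
    stats::integrate(function(u) dbinom(ki, n, qbeta(u, ab$alpha, ab$beta)),
                     0, 1, rel.tol = 1e-11, subdivisions = 2000L)$value,
    numeric(1))
}

# small word-trial table with known per-participant truth
make_word_table <- function(mu, rho, trials_per_p, n_tokens = 3, seed = 1) {
  rho <- rep(rho, length.out = length(mu))
  withr::with_seed(seed, {
    rows <- lapply(seq_along(mu), function(i) {
      k <- rbetabinom(trials_per_p, bb_params(n_tokens, mu[i], rho[i]))
      data.frame(participant_id = sprintf("P%02d", i),
                 trial_id = sprintf("word_%03d", seq_len(trials_per_p)),
                 n_tokens = n_tokens, n_correct = as.integer(k),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# exact leave-one-out log predictive density for the binomial model with a
# conjugate Beta prior: refitting without trial i gives a Beta posterior, so
# log p(y_i | y_-i) is a beta-binomial predictive in closed form
exact_loo_binomial <- function(trials, prior = c(2, 2)) {
  vapply(seq_len(nrow(trials)), function(i) {
    p <- trials$participant_id[i]
    others <- trials[-i, ]
    others <- others[others$participant_id == p, ]
    s <- prior[1] + sum(others$n_correct)
    f <- prior[2] + sum(others$n_tokens - others$n_correct)
    k <- trials$n_correct[i]; n <- trials$n_tokens[i]
    lchoose(n, k) + lbeta(s + k, f + n - k) - lbeta(s, f)
  }, numeric(1))
}

# generalized Pareto sampler (usual shape convention) for tail-fit tests
rgpd <- function(n, k, sigma = 1) {
  u <- stats::runif(n)
  if (abs(k) < 1e-12) -sigma * log(u) else sigma * (u^(-k) - 1) / k
}
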