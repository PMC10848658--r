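one_trial <- data.frame(participant_id = "P1", trial_id = "t1",
                        n_tokens = 3, n_correct = 1)

test_that("log_likelihood matches the per-trial pmf oracle", {
  ll <- log_likelihood(model_spec("binomial"), list(mu = 0.5), one_trial)
  expect_equal(ll$total, log(0.375), tolerance = 1e-12)

  # shared-rho model at rho -> 0 reproduces the binomial values
  tab <- make_word_table(c(0.4, 0.7), rho = 0.35, trials_per_p = 30, seed = 2)
  mus <- c(0.45, 0.68)
  bin <- log_likelihood(model_spec("binomial"), list(mu = mus), tab)
  bb0 <- log_likelihood(model_spec("bb-shared"),
                        list(mu = mus, rho = 1e-9), tab)
  expect_equal(bb0$pointwise, bin$pointwise, tolerance = 1e-6)

  # exhaustive independent recomputation, every model
  for (m in c("binomial", "bb-individual", "bb-shared", "bb-pooled")) {
    spec <- model_spec(m)
    pars <- switch(m,
      "binomial" = list(mu = mus),
      "bb-individual" = list(mu = mus, rho = c(0.2, 0.5)),
      "bb-shared" = list(mu = mus, rho = 0.35),
      "bb-pooled" = list(mu = 0.55, rho = 0.35))
    ll <- log_likelihood(spec, pars, tab)
    pid <- match(tab$participant_id, unique(tab$participant_id))
    mu_t <- if (m == "bb-pooled") rep(pars$mu, nrow(tab)) else pars$mu[pid]
    rho_t <- switch(m, "binomial" = rep(0, nrow(tab)),
                    "bb-individual" = pars$rho[pid],
                    rep(pars$rho, nrow(tab)))
    oracle <- vapply(seq_len(nrow(tab)), function(i)
      dbetabinom(tab$n_correct[i], tab$n_tokens[i], mu_t[i], rho_t[i],
                 log = TRUE), numeric(1))
    expect_equal(ll$pointwise, oracle, tolerance = 1e-10)
    expect_equal(ll$total, sum(oracle), tolerance = 1e-8)
  }
})

test_that("parameter/participant shape mismatches are rejected", {
  tab <- make_word_table(c(0.4, 0.7), 0.35, 10)
  expect_error(log_likelihood(model_spec("binomial"), list(mu = 0.5), tab),
               "expects 2 mu")
  expect_error(log_likelihood(model_spec("bb-shared"),
                              list(mu = c(0.4, 0.7), rho = c(0.1, 0.2)), tab),
               "rho")
  expect_error(log_likelihood(model_spec("bb-pooled"),
                              list(mu = c(0.4, 0.7), rho = 0.3), tab),
               "expects 1 mu")
})

test_that("log_prior is the sum of Beta(2,2) log densities", {
  m1 <- model_spec("binomial")
  expect_equal(log_prior(m1, list(mu = 0.5)), log(1.5), tolerance = 1e-12)
  expect_equal(log_prior(m1, list(mu = 0.25)), log(1.125), tolerance = 1e-12)
  expect_identical(log_prior(m1, list(mu = 0)), -Inf)
  expect_identical(log_prior(m1, list(mu = 1)), -Inf)
  expect_equal(log_prior(model_spec("bb-shared"),
                         list(mu = c(0.5, 0.25), rho = 0.5)),
               log(1.5) + log(1.125) + log(1.5), tolerance = 1e-12)
  # uniform prior contributes zero
  expect_equal(log_prior(m1, list(mu = 0.37), prior_shape = c(1, 1)), 0)
})

test_that("binomial MAP equals the conjugate closed form", {
  tab <- data.frame(participant_id = "P1",
                    trial_id = sprintf("w%03d", 1:300),
                    n_tokens = 3,
                    n_correct = rep(c(2, 1), each = 150))
  m <- fit_map(model_spec("binomial"), tab, n_starts = 3)
  expect_equal(unname(m$estimates), 451 / 902, tolerance = 1e-6)

  # degenerate all-correct participant: prior-regularized, finite
  perfect <- data.frame(participant_id = "P1",
                        trial_id = sprintf("w%02d", 1:40),
                        n_tokens = 3, n_correct = 3)
  mp <- fit_map(model_spec("binomial"), perfect, n_starts = 3)
  expect_true(is.finite(mp$log_posterior))
  expect_equal(unname(mp$estimates), 121 / 122, tolerance = 1e-5)
})

test_that("MAP is a local maximum and models nest in log posterior", {
  tab <- make_word_table(c(0.35, 0.55, 0.8), rho = 0.35, trials_per_p = 150,
                         seed = 6)
  maps <- lapply(c("bb-individual", "bb-shared", "bb-pooled"), function(m)
    fit_map(model_spec(m), tab, n_starts = 3))
  names(maps) <- c("bb-individual", "bb-shared", "bb-pooled")
  # nesting: richer models can only raise the maximum log posterior
  expect_gte(maps[["bb-individual"]]$log_posterior,
             maps[["bb-shared"]]$log_posterior - 1e-4)
  expect_gte(maps[["bb-shared"]]$log_posterior,
             maps[["bb-pooled"]]$log_posterior - 1e-4)
  # gradient-free check: no uphill neighbor on a small grid around the mode
  m3 <- maps[["bb-shared"]]
  spec <- model_spec("bb-shared")
  base <- m3$log_posterior
  for (j in seq_along(m3$theta)) {
    for (eps in c(-0.01, 0.01)) {
      th <- m3$theta; th[j] <- th[j] + eps
      par <- partialcredit:::unpack_theta(spec, m3$layout, th)
      neighbor <- log_likelihood(spec, par, tab)$total +
        log_prior(spec, par)
      expect_lte(neighbor, base + 1e-6)
    }
  }
})

test_that("posterior sampling matches the conjugate Beta posterior", {
  tab <- data.frame(participant_id = "P1",
                    trial_id = sprintf("w%02d", 1:60),
                    n_tokens = 1,
                    n_correct = rep(c(1, 0), times = c(20, 40)))
  fit <- fit_posterior(model_spec("binomial"), tab, n_chains = 4,
                       n_iterations = 2000, warmup = 500, seed = 31,
                       map_starts = 2)
  draws <- fit$draws[, 1]
  a <- 22; b <- 42
  true_mean <- a / (a + b)
  true_sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  mc_se <- true_sd / sqrt(fit$diagnostics$ess[1])
  expect_lt(abs(mean(draws) - true_mean), 4 * mc_se)
  expect_lt(abs(sd(draws) - true_sd), 0.15 * true_sd)
  # pointwise log-likelihood covers every trial
  expect_identical(ncol(fit$pointwise_loglik), nrow(tab))
})

test_that("default sampler configuration converges on the standard cohort", {
  ds <- generate_dataset(cohort_spec(seed = 42, sentence_trials = 0))
  fit <- fit_posterior(model_spec("bb-shared"), ds$trials, seed = 7)
  expect_true(all(fit$diagnostics$rhat < 1.01))
  expect_true(all(fit$diagnostics$ess > 400))
  expect_true(fit$converged)
  expect_false(fit$failed)
  # shared rho credible interval near truth, MAP close to KDE mode of draws
  rho_draws <- fit$draws[, "rho_group"]
  ci <- quantile(rho_draws, c(0.025, 0.975))
  expect_lt(abs(fit$map$estimates[["rho_group"]] - 0.35), 0.05)
  d <- density(rho_draws)
  kde_mode <- d$x[which.max(d$y)]
  expect_lt(abs(kde_mode - fit$map$estimates[["rho_group"]]), 0.02)
  # all draws inside their domains
  expect_true(all(fit$draws[, 1:20] > 0 & fit$draws[, 1:20] < 1))
  expect_true(all(rho_draws >= 0 & rho_draws < 1))
})

test_that("sampling is reproducible under a fixed seed", {
  tab <- make_word_table(c(0.4, 0.7), 0.35, 40, seed = 9)
  f1 <- suppressWarnings(
    fit_posterior(model_spec("bb-shared"), tab, n_chains = 2,
                  n_iterations = 400, warmup = 200, seed = 77,
                  map_starts = 2))
  f2 <- suppressWarnings(
    fit_posterior(model_spec("bb-shared"), tab, n_chains = 2,
                  n_iterations = 400, warmup = 200, seed = 77,
                  map_starts = 2))
  expect_identical(f1$draws, f2$draws)
})

test_that("MAP estimates are insensitive to the Beta(2,2) vs uniform prior", {
  ds <- generate_dataset(cohort_spec(seed = 12, sentence_trials = 0))
  spec <- model_spec("bb-shared")
  m_beta <- fit_map(spec, ds$trials, n_starts = 2)
  m_unif <- fit_map(spec, ds$trials, n_starts = 2, prior_shape = c(1, 1))
  expect_lt(max(abs(m_beta$estimates - m_unif$estimates)), 0.02)
})
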