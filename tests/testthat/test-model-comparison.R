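test_that("generalized Pareto tail fit recovers a known shape", {
  ks <- withr::with_seed(19, vapply(1:10, function(i)
    gpd_fit(rgpd(4000, k = 0.3))$k, numeric(1)))
  expect_lt(max(abs(ks - 0.3)), 0.1)
  # bounded-tail sample gives a negative shape
  k_neg <- withr::with_seed(4, gpd_fit(rgpd(4000, k = -0.25))$k)
  expect_lt(k_neg, 0)
  expect_true(is.na(gpd_fit(c(1, 2))$k))
})

test_that("psis_smooth handles degenerate tails and preserves order", {
  sm <- psis_smooth(rep(0.7, 100))
  expect_equal(exp(sm$log_weights), rep(0.01, 100), tolerance = 1e-12)
  expect_lte(sm$pareto_k, 0)

  lr <- withr::with_seed(8, rnorm(2000))
  sm <- psis_smooth(lr)
  expect_equal(sum(exp(sm$log_weights)), 1, tolerance = 1e-10)
  expect_identical(order(sm$log_weights), order(lr))
  # smoothed ratios are capped at the raw maximum, untouched off the tail
  expect_lte(max(sm$log_ratios_smoothed), max(lr) + 1e-10)
  M <- ceiling(3 * sqrt(2000))
  off_tail <- order(lr)[1:(2000 - M)]
  expect_equal(sm$log_ratios_smoothed[off_tail], lr[off_tail],
               tolerance = 1e-12)

  # too few draws: truncated fallback, k not estimable
  sm4 <- psis_smooth(c(0.1, 0.4, 0.2, 0.9))
  expect_true(is.na(sm4$pareto_k))
  expect_equal(sum(exp(sm4$log_weights)), 1, tolerance = 1e-12)
  expect_error(psis_smooth(c(1, Inf)), "finite")
})

test_that("elpd_loo on a certain model reduces to the log likelihood", {
  ll <- matrix(log(0.42), nrow = 50, ncol = 1)
  res <- elpd_loo(ll)
  expect_equal(res$elpd_loo, log(0.42), tolerance = 1e-12)
  expect_equal(res$p_loo, 0, tolerance = 1e-12)
})

test_that("PSIS-LOO matches the exact leave-one-out refit oracle", {
  # 3 participants x 10 trials; the binomial model with Beta(2,2) prior is
  # conjugate, so exact LOO refits have a closed form
  tab <- make_word_table(c(0.35, 0.55, 0.8), rho = 0, trials_per_p = 10,
                         seed = 14)
  fit <- fit_posterior(model_spec("binomial"), tab, n_chains = 4,
                       n_iterations = 3000, warmup = 1000, seed = 3,
                       map_starts = 2)
  res <- elpd_loo(fit)
  exact <- sum(exact_loo_binomial(tab))
  expect_lt(abs(res$elpd_loo - exact), 2 * res$elpd_se)
  expect_gte(res$p_loo, 0)
  expect_lte(res$elpd_loo, sum(res$pointwise$lpd))
  expect_identical(nrow(res$pointwise), nrow(tab))
  expect_true(all(is.finite(res$pointwise$pareto_k) |
                  is.na(res$pointwise$pareto_k)))
})

test_that("duplicating every trial approximately doubles elpd_loo", {
  tab <- make_word_table(c(0.4, 0.7), rho = 0.35, trials_per_p = 50, seed = 6)
  tab2 <- rbind(tab, transform(tab, trial_id = paste0(trial_id, "b")))
  f1 <- suppressWarnings(
    fit_posterior(model_spec("bb-shared"), tab, n_chains = 2,
                  n_iterations = 1200, warmup = 400, seed = 5,
                  map_starts = 2))
  f2 <- suppressWarnings(
    fit_posterior(model_spec("bb-shared"), tab2, n_chains = 2,
                  n_iterations = 1200, warmup = 400, seed = 5,
                  map_starts = 2))
  r1 <- elpd_loo(f1); r2 <- elpd_loo(f2)
  expect_lt(abs(r2$elpd_loo - 2 * r1$elpd_loo), 0.05 * abs(2 * r1$elpd_loo))
})

test_that("column de-duplication leaves the estimate unchanged", {
  withr::with_seed(23, {
    base <- matrix(rnorm(400 * 6, sd = 0.3), 400, 6)
    ll <- base[, c(1, 2, 2, 3, 1, 4, 5, 6, 3)]
  })
  with_groups <- elpd_loo(ll)
  one_by_one <- vapply(seq_len(ncol(ll)), function(j)
    elpd_loo(ll[, j, drop = FALSE])$elpd_loo, numeric(1))
  expect_equal(with_groups$pointwise$elpd, one_by_one, tolerance = 1e-10)
})

test_that("compare_models applies the delta-ELPD-greater-than-4 rule", {
  ll <- matrix(rnorm(200 * 20, sd = 0.1) - 1, 200, 20)
  self <- elpd_loo(ll)
  comp <- compare_models(list(a = self, b = self))
  expect_equal(comp$delta_elpd, c(0, 0))
  expect_equal(comp$delta_se, c(0, 0))
  expect_identical(comp$decision[2], "indistinguishable")

  short <- elpd_loo(ll[, 1:10])
  expect_error(compare_models(list(a = self, b = short)), "trial counts")
})

test_that("shared-rho data reproduce the qualitative comparison pattern", {
  ds <- generate_dataset(cohort_spec(n_participants = 8, word_trials = 120,
                                     sentence_trials = 0, seed = 33))
  fits <- lapply(c("binomial", "bb-individual", "bb-shared"), function(m)
    suppressWarnings(fit_posterior(model_spec(m), ds$trials, n_chains = 2,
                                   n_iterations = 900, warmup = 400,
                                   seed = 11, map_starts = 2)))
  loos <- lapply(fits, elpd_loo)
  names(loos) <- c("binomial", "bb-individual", "bb-shared")
  comp <- compare_models(loos)
  bin <- comp[comp$model == "binomial", ]
  expect_lt(bin$delta_elpd, -4)
  expect_lt(bin$delta_se, abs(bin$delta_elpd))
  expect_identical(bin$decision, "worse")
  # per-participant rho must not beat shared rho decisively
  if (comp$model[1] == "bb-individual") {
    expect_identical(comp[comp$model == "bb-shared", "decision"],
                     "indistinguishable")
  }
  # elpd_loo never exceeds the in-sample lpd
  for (l in loos) expect_gte(l$p_loo, 0)
})
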