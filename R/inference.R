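#' Generative models of trial-level token counts
#'
#' Four models of the count of correct tokens `X_tp` out of `n_t`:
#' \describe{
#'   \item{`binomial` (Model 1)}{`X_tp ~ Binomial(n_t, mu_p)` — per-participant
#'     accuracy, token outcomes independent.}
#'   \item{`bb-individual` (Model 2)}{`X_tp ~ BetaBinomial(n_t, mu_p, rho_p)` —
#'     per-participant accuracy and intraclass correlation.}
#'   \item{`bb-shared` (Model 3)}{`X_tp ~ BetaBinomial(n_t, mu_p, rho_group)` —
#'     per-participant accuracy, one shared intraclass correlation.}
#'   \item{`bb-pooled` (Model 4)}{`X_t ~ BetaBinomial(n_t, mu_group,
#'     rho_group)` — one accuracy and one correlation for the whole group.}
#' }
#' All probability/correlation parameters carry independent Beta(2, 2) priors
#' by default (weakly informative, vanishing at the boundaries).
#'
#' @name models
NULL

MODEL_NAMES <- c("binomial", "bb-individual", "bb-shared", "bb-pooled")

#' Construct a model specification
#'
#' @param model one of `"binomial"`, `"bb-individual"`, `"bb-shared"`,
#'   `"bb-pooled"`.
#' @return list of class `model_spec` with `name`, `family`, `mu_scope`,
#'   `rho_scope`.
#' @export
model_spec <- function(model = MODEL_NAMES) {
  model <- match.arg(model)
  switch(model,
    "binomial" = structure(list(name = model, family = "binomial",
                                mu_scope = "per_participant",
                                rho_scope = "none"), class = "model_spec"),
    "bb-individual" = structure(list(name = model, family = "betabinomial",
                                     mu_scope = "per_participant",
                                     rho_scope = "per_participant"),
                                class = "model_spec"),
    "bb-shared" = structure(list(name = model, family = "betabinomial",
                                 mu_scope = "per_participant",
                                 rho_scope = "group"), class = "model_spec"),
    "bb-pooled" = structure(list(name = model, family = "betabinomial",
                                 mu_scope = "group",
                                 rho_scope = "group"), class = "model_spec"))
}

# ---- internal model data ---------------------------------------------------
# Trials are aggregated to unique (participant, n_tokens, n_correct) cells:
# the log-likelihood is a frequency-weighted sum over cells, which makes a
# 5000-trial table as cheap as its handful of distinct count patterns.

build_model_data <- function(trials) {
  validate_trial_table(trials)
  pid <- factor(trials$participant_id, levels = unique(trials$participant_id))
  pid_idx <- as.integer(pid)
  key <- paste(pid_idx, trials$n_tokens, trials$n_correct)
  cell_keys <- unique(key)
  cell_of_trial <- match(key, cell_keys)
  first <- match(cell_keys, key)
  cells <- list(pid = pid_idx[first],
                n = as.integer(trials$n_tokens[first]),
                k = as.integer(trials$n_correct[first]),
                freq = as.vector(table(factor(cell_of_trial,
                                              levels = seq_along(cell_keys)))))
  cells$lchoose <- lchoose(cells$n, cells$k)
  list(participants = levels(pid), P = nlevels(pid), T = nrow(trials),
       cells = cells, cell_of_trial = cell_of_trial,
       trials_per_p = as.vector(table(pid)))
}

# per-cell log pmf given per-participant mu (length P) and rho (length P or
# NULL for the binomial family)
cell_loglik <- function(data, mu, rho) {
  cl <- data$cells
  if (is.null(rho)) {
    stats::dbinom(cl$k, cl$n, mu[cl$pid], log = TRUE)
  } else {
    # below ~1e-8 the lgamma differences cancel catastrophically; the
    # binomial limit is exact to that order
    bin <- rho < 1e-8
    rho_safe <- pmax(rho, 1e-8)
    s <- 1 / rho_safe - 1
    a <- mu * s; b <- (1 - mu) * s
    lp <- cl$lchoose + lbeta(cl$k + a[cl$pid], cl$n - cl$k + b[cl$pid]) -
      lbeta(a, b)[cl$pid]
    if (any(bin)) {
      idx <- bin[cl$pid]
      lp[idx] <- stats::dbinom(cl$k[idx], cl$n[idx], mu[cl$pid[idx]],
                               log = TRUE)
    }
    lp
  }
}

# per-participant log-likelihood vector (length P)
participant_loglik <- function(data, mu, rho) {
  lp <- cell_loglik(data, mu, rho)
  out <- numeric(data$P)
  agg <- rowsum(data$cells$freq * lp, data$cells$pid)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

expand_mu <- function(spec, data, mu) {
  if (spec$mu_scope == "group") rep(mu, data$P) else mu
}
expand_rho <- function(spec, data, rho) {
  if (spec$rho_scope == "none") NULL
  else if (spec$rho_scope == "group") rep(rho, data$P) else rho
}

check_param_dims <- function(spec, data, parameters) {
  need_mu <- if (spec$mu_scope == "group") 1L else data$P
  if (length(parameters$mu) != need_mu)
    stop_domain("model '%s' expects %d mu parameter(s), got %d",
                spec$name, need_mu, length(parameters$mu))
  need_rho <- switch(spec$rho_scope, none = 0L, group = 1L,
                     per_participant = data$P)
  got_rho <- length(parameters$rho)
  if (got_rho != need_rho)
    stop_domain("model '%s' expects %d rho parameter(s), got %d",
                spec$name, need_rho, got_rho)
}

#' Log-likelihood of a model at given parameter values
#'
#' @param spec a [model_spec()].
#' @param parameters list with `mu` (scalar for group scope, else one value
#'   per participant in order of first appearance) and `rho` (scalar, vector,
#'   or `NULL` for the binomial model).
#' @param trials trial table data.frame.
#' @return list with `total` and `pointwise` (one log density per trial, in
#'   table order).
#' @export
log_likelihood <- function(spec, parameters, trials) {
  stopifnot(inherits(spec, "model_spec"))
  data <- build_model_data(trials)
  check_param_dims(spec, data, parameters)
  mu <- expand_mu(spec, data, parameters$mu)
  rho <- expand_rho(spec, data, parameters$rho)
  lp_cell <- cell_loglik(data, mu, rho)
  pointwise <- lp_cell[data$cell_of_trial]
  list(total = sum(pointwise), pointwise = pointwise)
}

#' Log prior density of a model's parameters
#'
#' Independent `Beta(shape1, shape2)` priors (default Beta(2, 2)) on every mu
#' and rho parameter. Boundary values give `-Inf` without numerical faults.
#'
#' @param spec a [model_spec()].
#' @param parameters list with `mu` and (where applicable) `rho`.
#' @param prior_shape length-2 beta shape, default `c(2, 2)`; `c(1, 1)` is the
#'   uniform prior used for sensitivity checks.
#' @return scalar log prior density.
#' @export
log_prior <- function(spec, parameters, prior_shape = c(2, 2)) {
  stopifnot(inherits(spec, "model_spec"))
  vals <- c(parameters$mu, parameters$rho)
  sum(stats::dbeta(vals, prior_shape[1], prior_shape[2], log = TRUE))
}

# ---- parameter packing (unconstrained logit scale) -------------------------

param_layout <- function(spec, data) {
  mu_names <- if (spec$mu_scope == "group") "mu_group"
              else paste0("mu[", data$participants, "]")
  rho_names <- switch(spec$rho_scope,
                      none = character(0),
                      group = "rho_group",
                      per_participant = paste0("rho[", data$participants, "]"))
  list(mu_idx = seq_along(mu_names),
       rho_idx = if (length(rho_names)) length(mu_names) + seq_along(rho_names)
                 else integer(0),
       names = c(mu_names, rho_names))
}

RHO_CAP <- 1 - 1e-6

unpack_theta <- function(spec, layout, theta) {
  mu <- inv_logit(theta[layout$mu_idx])
  rho <- if (length(layout$rho_idx)) pmin(inv_logit(theta[layout$rho_idx]),
                                          RHO_CAP)
         else NULL
  list(mu = mu, rho = rho)
}

# log posterior in constrained coordinates (the density whose mode is the
# MAP); theta is the unconstrained optimizer variable
log_post_constrained <- function(spec, data, layout, theta, prior_shape) {
  par <- unpack_theta(spec, layout, theta)
  mu <- expand_mu(spec, data, par$mu)
  rho <- expand_rho(spec, data, par$rho)
  sum(participant_loglik(data, mu, rho)) +
    log_prior(spec, par, prior_shape)
}

#' Maximum a posteriori estimate by multi-start optimization
#'
#' Optimizes the log posterior (likelihood plus Beta priors, density taken in
#' the constrained mu/rho coordinates so the conjugate binomial case recovers
#' the textbook `(successes + 1) / (total + 2)` mode) over a logit transform
#' of all parameters, from `n_starts` starting points: one
#' empirical-proportion start plus random restarts. Best log posterior wins;
#' ties broken by start order.
#'
#' @param spec a [model_spec()].
#' @param trials trial table data.frame.
#' @param seed integer seed for the random restarts.
#' @param n_starts number of optimizer starts (default 8).
#' @param prior_shape beta prior shape, default `c(2, 2)`.
#' @return list of class `pc_map` with `estimates` (named, constrained),
#'   `log_posterior`, `model`, `convergence` (per start), `best_start`.
#' @export
fit_map <- function(spec, trials, seed = 1L, n_starts = 8,
                    prior_shape = c(2, 2)) {
  stopifnot(inherits(spec, "model_spec"))
  data <- build_model_data(trials)
  layout <- param_layout(spec, data)
  K <- length(layout$names)

  # empirical start: prior-regularized per-participant proportions
  succ <- rowsum(trials$n_correct,
                 factor(trials$participant_id, levels = data$participants))[, 1]
  tot <- rowsum(trials$n_tokens,
                factor(trials$participant_id, levels = data$participants))[, 1]
  p_hat <- (succ + 1) / (tot + 2)
  mu0 <- if (spec$mu_scope == "group") sum(succ + 1) / sum(tot + 2) else p_hat
  theta0 <- numeric(K)
  theta0[layout$mu_idx] <- logit(mu0)
  if (length(layout$rho_idx)) theta0[layout$rho_idx] <- logit(0.25)

  starts <- withr::with_seed(as.integer(seed), {
    extra <- if (n_starts > 1)
      replicate(n_starts - 1, stats::rnorm(K, 0, 1.5), simplify = FALSE)
    else list()
    c(list(theta0), extra)
  })

  neg <- function(theta) -log_post_constrained(spec, data, layout, theta,
                                               prior_shape)
  fits <- lapply(starts, function(th) {
    stats::optim(th, neg, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
  })
  values <- vapply(fits, function(f) -f$value, numeric(1))
  conv <- vapply(fits, function(f) f$convergence, numeric(1))
  if (all(!is.finite(values)))
    stop_domain("MAP optimization failed to find a finite posterior after %d starts",
                n_starts)
  best <- which.max(values)  # first index wins ties
  par <- unpack_theta(spec, layout, fits[[best]]$par)
  est <- stats::setNames(c(par$mu, par$rho), layout$names)
  structure(list(estimates = est, theta = fits[[best]]$par,
                 log_posterior = values[best], model = spec,
                 convergence = conv, best_start = best,
                 prior_shape = prior_shape, layout = layout),
            class = "pc_map")
}

# ---- adaptive random-walk Metropolis ---------------------------------------

jac_logit <- function(p) log(p) + log1p(-p)

#' Posterior sampling by adaptive random-walk Metropolis
#'
#' Gaussian random-walk proposals on the logit scale (with Jacobian
#' correction), updated blockwise: because participants are conditionally
#' independent given any shared parameters, all per-participant mu (and rho)
#' proposals are made simultaneously and accepted or rejected element-wise;
#' shared group parameters are updated as scalars against the full
#' likelihood. Per-parameter proposal scales are tuned during warmup toward
#' ~0.3 acceptance and then frozen. Chains are initialized by jittering the
#' MAP.
#'
#' @param spec a [model_spec()].
#' @param trials trial table data.frame.
#' @param n_chains number of chains (default 4).
#' @param n_iterations iterations per chain including warmup (default 2500).
#' @param warmup warmup (adaptation) iterations discarded per chain
#'   (default 1000).
#' @param seed integer seed; identical seed and configuration reproduce the
#'   draws exactly.
#' @param prior_shape beta prior shape, default `c(2, 2)`.
#' @param compute_loglik populate the pointwise log-likelihood matrix
#'   (default TRUE; needed for PSIS-LOO).
#' @param map optional precomputed [fit_map()] result to skip refitting.
#' @param map_starts optimizer starts when the MAP is fit here (default 4).
#' @return object of class `pc_fit`: `draws` (matrix, one row per retained
#'   draw across chains, named columns plus `lp__`), `map`, `diagnostics`
#'   (per-parameter split-Rhat and ESS), `converged`/`failed` flags,
#'   `pointwise_loglik` (draws x trials), `trial_groups` (duplicate-column
#'   index used by LOO), `seed`, `config`.
#' @export
fit_posterior <- function(spec, trials, n_chains = 4, n_iterations = 2500,
                          warmup = 1000, seed = 1L, prior_shape = c(2, 2),
                          compute_loglik = TRUE, map = NULL, map_starts = 4) {
  stopifnot(inherits(spec, "model_spec"), warmup < n_iterations)
  data <- build_model_data(trials)
  layout <- param_layout(spec, data)
  K <- length(layout$names)
  if (is.null(map))
    map <- fit_map(spec, trials, seed = seed, n_starts = map_starts,
                   prior_shape = prior_shape)

  n_keep <- n_iterations - warmup
  mu_scalar <- spec$mu_scope == "group"
  rho_kind <- spec$rho_scope
  s1 <- prior_shape[1]; s2 <- prior_shape[2]

  run_chain <- function(theta_init) {
    th_mu <- theta_init[layout$mu_idx]
    th_rho <- theta_init[layout$rho_idx]
    mu <- inv_logit(th_mu)
    rho <- if (length(th_rho)) pmin(inv_logit(th_rho), RHO_CAP) else NULL
    mu_full <- expand_mu(spec, data, mu)
    rho_full <- expand_rho(spec, data, rho)
    lik_p <- participant_loglik(data, mu_full, rho_full)

    sc_mu <- rep(0.5, length(th_mu))
    sc_rho <- rep(0.5, length(th_rho))
    acc_mu <- numeric(length(th_mu)); acc_rho <- numeric(length(th_rho))
    batch <- 0L; batch_len <- 50L
    out <- matrix(NA_real_, n_keep, K + 1)

    for (it in seq_len(n_iterations)) {
      ## mu block
      prop_th <- th_mu + sc_mu * stats::rnorm(length(th_mu))
      prop_mu <- inv_logit(prop_th)
      prop_mu_full <- expand_mu(spec, data, prop_mu)
      prop_lik <- participant_loglik(data, prop_mu_full, rho_full)
      if (mu_scalar) {
        delta <- sum(prop_lik) - sum(lik_p) +
          stats::dbeta(prop_mu, s1, s2, log = TRUE) -
          stats::dbeta(mu, s1, s2, log = TRUE) +
          jac_logit(prop_mu) - jac_logit(mu)
        if (log(stats::runif(1)) < delta) {
          th_mu <- prop_th; mu <- prop_mu; mu_full <- prop_mu_full
          lik_p <- prop_lik; acc_mu <- acc_mu + 1
        }
      } else {
        delta <- prop_lik - lik_p +
          stats::dbeta(prop_mu, s1, s2, log = TRUE) -
          stats::dbeta(mu, s1, s2, log = TRUE) +
          jac_logit(prop_mu) - jac_logit(mu)
        acc <- log(stats::runif(length(delta))) < delta
        if (any(acc)) {
          th_mu[acc] <- prop_th[acc]; mu[acc] <- prop_mu[acc]
          mu_full <- mu
          lik_p[acc] <- prop_lik[acc]
          acc_mu[acc] <- acc_mu[acc] + 1
        }
      }
      ## rho block
      if (rho_kind != "none") {
        prop_th <- th_rho + sc_rho * stats::rnorm(length(th_rho))
        prop_rho <- pmin(inv_logit(prop_th), RHO_CAP)
        if (rho_kind == "group") {
          prop_lik <- participant_loglik(data, mu_full,
                                         rep(prop_rho, data$P))
          delta <- sum(prop_lik) - sum(lik_p) +
            stats::dbeta(prop_rho, s1, s2, log = TRUE) -
            stats::dbeta(rho, s1, s2, log = TRUE) +
            jac_logit(prop_rho) - jac_logit(rho)
          if (log(stats::runif(1)) < delta) {
            th_rho <- prop_th; rho <- prop_rho
            rho_full <- rep(rho, data$P)
            lik_p <- prop_lik; acc_rho <- acc_rho + 1
          }
        } else {
          prop_lik <- participant_loglik(data, mu_full, prop_rho)
          delta <- prop_lik - lik_p +
            stats::dbeta(prop_rho, s1, s2, log = TRUE) -
            stats::dbeta(rho, s1, s2, log = TRUE) +
            jac_logit(prop_rho) - jac_logit(rho)
          acc <- log(stats::runif(length(delta))) < delta
          if (any(acc)) {
            th_rho[acc] <- prop_th[acc]; rho[acc] <- prop_rho[acc]
            rho_full <- rho
            lik_p[acc] <- prop_lik[acc]
            acc_rho[acc] <- acc_rho[acc] + 1
          }
        }
      }
      ## warmup adaptation toward ~0.3 acceptance
      if (it <= warmup && it %% batch_len == 0L) {
        batch <- batch + 1L
        rate <- 1 / sqrt(batch)
        sc_mu <- sc_mu * exp(rate * (acc_mu / batch_len - 0.3))
        if (length(sc_rho))
          sc_rho <- sc_rho * exp(rate * (acc_rho / batch_len - 0.3))
        acc_mu[] <- 0; acc_rho[] <- 0
      }
      if (it > warmup) {
        lp <- sum(lik_p) +
          sum(stats::dbeta(c(mu, rho), s1, s2, log = TRUE))
        out[it - warmup, ] <- c(mu, rho, lp)
      }
    }
    out
  }

  chains <- withr::with_seed(as.integer(seed), {
    inits <- lapply(seq_len(n_chains), function(c)
      map$theta + stats::rnorm(K, 0, 0.1))
    lapply(inits, run_chain)
  })

  draws <- do.call(rbind, chains)
  colnames(draws) <- c(layout$names, "lp__")
  diag_df <- data.frame(
    parameter = layout$names,
    rhat = vapply(seq_len(K), function(j)
      split_rhat(sapply(chains, function(ch) ch[, j])), numeric(1)),
    ess = vapply(seq_len(K), function(j)
      ess_draws(sapply(chains, function(ch) ch[, j])), numeric(1)),
    stringsAsFactors = FALSE)
  converged <- all(diag_df$rhat < 1.01, na.rm = TRUE) &&
    all(diag_df$ess > 400, na.rm = TRUE)
  failed <- any(diag_df$rhat >= 1.05, na.rm = TRUE)
  if (!converged && n_chains > 1)
    warning(sprintf(
      "convergence warning for model '%s': max Rhat = %.3f, min ESS = %.0f",
      spec$name, max(diag_df$rhat, na.rm = TRUE),
      min(diag_df$ess, na.rm = TRUE)), call. = FALSE)

  pointwise <- NULL
  if (compute_loglik)
    pointwise <- pointwise_loglik_matrix(spec, data, layout, draws)

  structure(list(model = spec, draws = draws, map = map,
                 diagnostics = diag_df, converged = converged,
                 failed = failed, pointwise_loglik = pointwise,
                 trial_groups = data$cell_of_trial,
                 participants = data$participants, seed = as.integer(seed),
                 config = list(n_chains = n_chains,
                               n_iterations = n_iterations, warmup = warmup,
                               prior_shape = prior_shape)),
            class = "pc_fit")
}

# draws x trials log-likelihood matrix, computed on the unique count cells
# and expanded to trial columns
pointwise_loglik_matrix <- function(spec, data, layout, draws) {
  S <- nrow(draws)
  cl <- data$cells
  mu_d <- draws[, layout$mu_idx, drop = FALSE]
  if (spec$mu_scope == "group") mu_d <- mu_d[, rep(1, data$P), drop = FALSE]
  if (spec$rho_scope == "none") {
    MU <- mu_d[, cl$pid, drop = FALSE]
    lp <- matrix(stats::dbinom(rep(cl$k, each = S), rep(cl$n, each = S),
                               MU, log = TRUE), S)
  } else {
    rho_d <- draws[, layout$rho_idx, drop = FALSE]
    if (spec$rho_scope == "group") rho_d <- rho_d[, rep(1, data$P),
                                                  drop = FALSE]
    sd_ <- 1 / rho_d - 1
    a <- mu_d * sd_; b <- (1 - mu_d) * sd_
    A <- a[, cl$pid, drop = FALSE]; B <- b[, cl$pid, drop = FALSE]
    lp <- rep(cl$lchoose, each = S) +
      lbeta(sweep(A, 2, cl$k, "+"), sweep(B, 2, cl$n - cl$k, "+")) -
      lbeta(A, B)
  }
  lp[, data$cell_of_trial, drop = FALSE]
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf("partialcredit posterior fit: model '%s'\n", x$model$name))
  cat(sprintf("  %d retained draws (%d chains), %d parameters\n",
              nrow(x$draws), x$config$n_chains, ncol(x$draws) - 1))
  cat(sprintf("  max Rhat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE),
              if (x$failed) "  [CONVERGENCE FAILURE]"
              else if (!x$converged) "  [convergence warning]" else ""))
  invisible(x)
}

#' Posterior summary of a fit
#'
#' @param object a `pc_fit`.
#' @param probs credible-interval quantiles.
#' @param ... unused.
#' @return data.frame with MAP, posterior mean, sd, quantiles and diagnostics
#'   per parameter.
#' @export
summary.pc_fit <- function(object, probs = c(0.025, 0.975), ...) {
  params <- object$diagnostics$parameter
  d <- object$draws[, params, drop = FALSE]
  qs <- t(apply(d, 2, stats::quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  data.frame(parameter = params,
             map = unname(object$map$estimates[params]),
             mean = colMeans(d),
             sd = apply(d, 2, stats::sd), qs,
             rhat = object$diagnostics$rhat,
             ess = object$diagnostics$ess,
             row.names = NULL, stringsAsFactors = FALSE)
}
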