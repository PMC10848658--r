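#' Measurement precision of partial-credit scoring
#'
#' How precisely does a test list of `W` words estimate a listener's mean
#' accuracy? With `n` tokens per word and intraclass correlation `rho`, mean
#' accuracy over a list (total tokens correct / total tokens) has standard
#' deviation `sqrt(mu (1 - mu) (1 + (n - 1) rho) / (n W))`: the binomial
#' standard error shrunk by the extra tokens but inflated by the design
#' effect `1 + (n - 1) rho`. At `rho = 0`, three-phoneme scoring of `W` words
#' is worth `3 W` whole-word trials; as `rho` grows that benefit erodes.
#'
#' @name precision
NULL

#' Analytic SD of mean accuracy for a W-word list
#'
#' @param n tokens per word (1 = whole-word scoring, 3 = phoneme scoring of
#'   CNC words).
#' @param mu mean per-token accuracy.
#' @param rho intraclass correlation in \[0, 1).
#' @param words number of words tested (>= 1), may be a vector.
#' @return SD of mean accuracy (same length as `words`).
#' @examples
#' analytic_sd_of_mean(1, 0.5, 0, 50)   # ~0.0707, the clinical 50-word list
#' @export
analytic_sd_of_mean <- function(n, mu, rho, words) {
  if (any(words < 1)) stop_domain("`words` must be >= 1")
  sqrt(mu * (1 - mu) * (1 + (n - 1) * rho) / (n * words))
}

#' Monte-Carlo SD of mean accuracy across a grid of list lengths
#'
#' For each word count `W`, draws `n_draws` replicate test lists of `W`
#' trials from the two-stage beta-binomial scheme, computes mean accuracy per
#' replicate (total tokens correct / total tokens) and takes the SD across
#' replicates.
#'
#' @param n tokens per word.
#' @param mu mean per-token accuracy.
#' @param rho intraclass correlation.
#' @param words_grid integer vector of list lengths (default 10:100).
#' @param n_draws replicate lists per grid point (default 10000).
#' @param seed integer seed.
#' @return list of class `precision_curve` with `words`, `sd_simulated`,
#'   `sd_analytic` and the generating parameters.
#' @export
simulate_sd_of_mean <- function(n, mu, rho, words_grid = 10:100,
                                n_draws = 10000, seed = 1L) {
  if (n_draws < 2) stop_domain("`n_draws` must be >= 2")
  if (any(words_grid < 1)) stop_domain("`words_grid` must be >= 1")
  sd_sim <- withr::with_seed(as.integer(seed), {
    vapply(words_grid, function(W) {
      total <- W * n_draws
      pi <- if (rho == 0) rep(mu, total) else {
        ab <- mu_rho_to_alpha_beta(mu, rho)
        stats::rbeta(total, ab$alpha, ab$beta)
      }
      counts <- matrix(stats::rbinom(total, n, pi), nrow = W)
      stats::sd(colSums(counts) / (n * W))
    }, numeric(1))
  })
  structure(list(words = as.integer(words_grid), sd_simulated = sd_sim,
                 sd_analytic = analytic_sd_of_mean(n, mu, rho, words_grid),
                 n = n, mu = mu, rho = rho, n_draws = n_draws,
                 seed = as.integer(seed)),
            class = "precision_curve")
}

#' Minimum list length matching a reference precision
#'
#' Smallest integer `W` whose SD of mean accuracy does not exceed
#' `target_sd`. On the analytic formula this is
#' `ceiling(mu (1 - mu) (1 + (n - 1) rho) / (n target_sd^2))`; on a simulated
#' curve it is the first grid point at or below the target.
#'
#' @param target_sd reference SD to match; defaults to whole-word scoring of
#'   a 50-word list at `mu` (the common clinical reference).
#' @param curve optional `precision_curve` from [simulate_sd_of_mean()]; when
#'   supplied the minimum is read off the simulated curve, otherwise the
#'   analytic closed form is used.
#' @param n,mu,rho distribution parameters (taken from `curve` when given).
#' @param search_range integer range searched on a simulated curve.
#' @return smallest matching integer word count.
#' @export
min_words_to_match <- function(target_sd = NULL, curve = NULL, n = 3,
                               mu = 0.5, rho = 0,
                               search_range = c(1, 10000)) {
  if (is.null(target_sd))
    target_sd <- analytic_sd_of_mean(1, mu, 0, 50)
  if (target_sd <= 0) stop_domain("`target_sd` must be positive")
  if (is.null(curve)) {
    W <- ceiling(mu * (1 - mu) * (1 + (n - 1) * rho) / (n * target_sd^2))
    return(as.integer(max(1L, W)))
  }
  idx <- which(curve$words >= search_range[1] & curve$words <= search_range[2])
  ok <- idx[curve$sd_simulated[idx] <= target_sd]
  if (!length(ok)) {
    closest <- idx[which.min(curve$sd_simulated[idx])]
    stop_domain(
      "no word count in [%d, %d] reaches SD <= %.4g (closest: %.4g at W = %d)",
      search_range[1], search_range[2], target_sd,
      curve$sd_simulated[closest], curve$words[closest])
  }
  curve$words[min(ok)]
}

#' The list-length planning analysis for phoneme vs whole-word scoring
#'
#' Reproduces the full precision analysis: simulate the SD-of-the-mean curve
#' for whole-word scoring (`Binomial(n = 1, mu)`) and phoneme scoring
#' (`BetaBinomial(n = 3, mu, rho)`) over a grid of list lengths, then find
#' the minimum number of phoneme-scored words matching the whole-word SD at
#' the 50-word reference. Both the Monte-Carlo and the analytic minima are
#' reported (near the crossing the Monte-Carlo estimate is noisy, so they can
#' differ by a word).
#'
#' @param mu mean per-token accuracy (default 0.5, where binomial SD peaks).
#' @param rho intraclass correlation for phoneme scoring (default 0.35, the
#'   shared estimate for CNC words).
#' @param n_phonemes tokens per word under partial-credit scoring (default 3).
#' @param reference_words whole-word list length to match (default 50).
#' @param words_grid grid of list lengths (default 10:100).
#' @param n_draws Monte-Carlo replicates per grid point (default 10000).
#' @param seed integer seed.
#' @return list of class `precision_analysis`: both curves, the reference SD,
#'   simulated and analytic minimum word counts, and whether they differ.
#' @export
precision_analysis <- function(mu = 0.5, rho = 0.35, n_phonemes = 3,
                               reference_words = 50, words_grid = 10:100,
                               n_draws = 10000, seed = 1L) {
  seeds <- spawn_seeds(seed, c("whole_word", "phoneme"))
  whole <- simulate_sd_of_mean(1, mu, 0, words_grid, n_draws,
                               seeds[["whole_word"]])
  phoneme <- simulate_sd_of_mean(n_phonemes, mu, rho, words_grid, n_draws,
                                 seeds[["phoneme"]])
  ref_idx <- match(reference_words, whole$words)
  target_sim <- if (!is.na(ref_idx)) whole$sd_simulated[ref_idx]
                else stop_domain("`reference_words` must lie on `words_grid`")
  target_analytic <- analytic_sd_of_mean(1, mu, 0, reference_words)
  min_sim <- min_words_to_match(target_sim, curve = phoneme,
                                search_range = range(words_grid))
  min_analytic <- min_words_to_match(target_analytic, n = n_phonemes,
                                     mu = mu, rho = rho)
  structure(list(whole_word = whole, phoneme = phoneme,
                 reference_words = reference_words,
                 target_sd_simulated = target_sim,
                 target_sd_analytic = target_analytic,
                 min_words_simulated = as.integer(min_sim),
                 min_words_analytic = as.integer(min_analytic),
                 differ = min_sim != min_analytic),
            class = "precision_analysis")
}

#' @export
print.precision_analysis <- function(x, ...) {
  cat(sprintf(
    "Precision of phoneme vs whole-word scoring (mu = %.2f, rho = %.2f)\n",
    x$phoneme$mu, x$phoneme$rho))
  cat(sprintf("  reference: whole-word SD at %d words = %.4f (simulated %.4f)\n",
              x$reference_words, x$target_sd_analytic, x$target_sd_simulated))
  cat(sprintf("  minimum phoneme-scored words: %d simulated, %d analytic%s\n",
              x$min_words_simulated, x$min_words_analytic,
              if (x$differ) "  [differ near the crossing]" else ""))
  invisible(x)
}
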