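# MCMC convergence diagnostics: split-Rhat and Geyer initial-monotone ESS.
# Draws are passed as an iterations x chains matrix per parameter.

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1):n, , drop = FALSE])
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' @param mat iterations x chains matrix of draws for one parameter.
#' @return scalar Rhat (NA if degenerate).
#' @export
split_rhat <- function(mat) {
  mat <- split_chains(as.matrix(mat))
  n <- nrow(mat); m <- ncol(mat)
  if (n < 2) return(NA_real_)
  means <- colMeans(mat)
  vars <- apply(mat, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= .Machine$double.eps) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Geyer initial-monotone-positive-sequence ESS for a single chain.
ess_one_chain <- function(x) {
  n <- length(x)
  if (stats::var(x) <= .Machine$double.eps) return(NA_real_)
  max_lag <- min(n - 1, 400)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
  # pair consecutive lags; keep while the paired sums stay positive and
  # non-increasing
  n_pairs <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (i in seq_len(n_pairs)) {
    g <- rho[2 * i - 1] + rho[2 * i]
    if (g < 0) break
    g <- min(g, prev)
    prev <- g
    tau <- tau + 2 * g
  }
  n / tau
}

#' Effective sample size across chains
#'
#' Sum of per-chain Geyer initial-monotone estimates (conservative relative
#' to cross-chain estimators, adequate for low-dimensional targets).
#'
#' @param mat iterations x chains matrix of draws for one parameter.
#' @return scalar ESS.
#' @export
ess_draws <- function(mat) {
  mat <- as.matrix(mat)
  per_chain <- apply(mat, 2, ess_one_chain)
  if (all(is.na(per_chain))) return(NA_real_)
  sum(per_chain, na.rm = TRUE)
}
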