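#' @keywords internal
"_PACKAGE"

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) matrixStats::logSumExp(x)

logit <- function(p) log(p) - log1p(-p)

inv_logit <- function(x) {
  # stable plogis-equivalent; keeps values strictly inside (0, 1)
  p <- stats::plogis(x)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Derive per-stage seeds from a master seed
#'
#' A master seed deterministically spawns a named vector of sub-seeds, one per
#' pipeline stage, so stages can be re-run independently while the whole run
#' stays reproducible. Sub-seeds are drawn as `sample.int(.Machine$integer.max,
#' n)` under the master seed.
#'
#' @param master_seed single integer.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds.
#' @export
spawn_seeds <- function(master_seed, stages) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed))
  seeds <- withr::with_seed(
    as.integer(master_seed),
    sample.int(.Machine$integer.max, length(stages))
  )
  stats::setNames(as.integer(seeds), stages)
}

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
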