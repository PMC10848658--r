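#' Trial tables
#'
#' The central data container: one row per stimulus presentation with
#' `participant_id`, `trial_id`, `n_tokens` (tokens presented) and `n_correct`
#' (tokens correctly identified), satisfying `0 <= n_correct <= n_tokens`.
#'
#' @name trial_table
NULL

trial_table_cols <- c("participant_id", "trial_id", "n_tokens", "n_correct")

#' Validate a trial table
#'
#' @param trials data.frame.
#' @return the validated table, invisibly usable in pipelines.
#' @export
validate_trial_table <- function(trials) {
  missing <- setdiff(trial_table_cols, names(trials))
  if (length(missing))
    stop_domain("trial table misses column(s): %s",
                paste(missing, collapse = ", "))
  n <- trials$n_tokens; k <- trials$n_correct
  bad <- which(!is.finite(n) | n < 1 | n != round(n) |
               !is.finite(k) | k < 0 | k > n | k != round(k))
  if (length(bad))
    stop_domain(
      "trial table row %d violates 0 <= n_correct <= n_tokens (n_tokens = %s, n_correct = %s)",
      bad[1], format(n[bad[1]]), format(k[bad[1]]))
  trials
}

#' Read / write a trial table CSV
#'
#' Plain CSV with the four canonical columns; reading validates the count
#' invariants and reports the first offending row.
#'
#' @param path file path.
#' @return `read_trial_table` returns the validated data.frame;
#'   `write_trial_table` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_table_cols, names(df))
  if (length(missing))
    stop_domain("trial table %s misses column(s): %s", path,
                paste(missing, collapse = ", "))
  for (col in c("n_tokens", "n_correct")) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop_domain("trial table %s: column %s is not numeric (first bad row %d)",
                  path, col, which(!grepl("^-?[0-9]+$", as.character(v)))[1])
  }
  validate_trial_table(df[trial_table_cols])
}

#' @rdname read_trial_table
#' @param trials trial table data.frame.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  utils::write.csv(trials[trial_table_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
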