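#' Token-level scoring of transcribed responses
#'
#' Word responses (phoneme tokens) are scored by edit distance: the number of
#' phonemes correct is the target length minus the number of edits needed to
#' transform the response into the target, floored at zero. Sentence responses
#' are scored by the number of keywords present in the response, each response
#' token consumable at most once.
#'
#' @name scoring
NULL

#' Levenshtein edit distance between two token sequences
#'
#' Unit-cost insertion, deletion and substitution, computed by dynamic
#' programming over tokens compared with exact equality. The token alphabet is
#' opaque: phonemes in any transcription scheme, orthographic words, anything.
#'
#' @param a,b character vectors of tokens (either may be empty).
#' @return non-negative integer; 0 iff the sequences are equal.
#' @examples
#' edit_distance(c("b", "ae", "t"), c("p", "ae", "t"))  # 1
#' @export
edit_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  la <- length(a); lb <- length(b)
  if (la == 0) return(lb)
  if (lb == 0) return(la)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- integer(lb + 1)
    cur[1] <- i
    cost <- as.integer(a[i] != b)          # substitution costs, row i
    for (j in seq_len(lb)) {
      cur[j + 1] <- min(prev[j + 1] + 1L,  # deletion from a
                        cur[j] + 1L,       # insertion into a
                        prev[j] + cost[j]) # substitution / match
    }
    prev <- cur
  }
  prev[lb + 1]
}

#' Score one word trial by phonemes correct
#'
#' `n_correct = max(0, length(target) - edit_distance(response, target))`.
#' For three-phoneme CNC words this is "three minus the number of edits, to a
#' minimum of zero".
#'
#' @param target character vector of target tokens (non-empty).
#' @param response character vector of response tokens (may be empty).
#' @return list with `n_tokens` and `n_correct`.
#' @export
score_word <- function(target, response) {
  if (length(target) == 0) stop_domain("target token sequence must be non-empty")
  n <- length(target)
  list(n_tokens = n,
       n_correct = max(0L, n - edit_distance(response, target)))
}

#' Score one sentence trial by keywords correct
#'
#' Counts how many target keywords appear in the response, case-insensitively,
#' with each response token consumable at most once (a response containing one
#' "dog" matches at most one "dog" keyword). With exact-match equality this
#' multiset intersection equals the maximum bipartite matching.
#'
#' @param keywords character vector of target keywords (non-empty).
#' @param response character vector of response tokens (may be empty).
#' @return list with `n_tokens` (number of keywords) and `n_correct`.
#' @export
score_sentence_keywords <- function(keywords, response) {
  if (length(keywords) == 0) stop_domain("keyword sequence must be non-empty")
  kw <- table(tolower(keywords))
  rs <- table(tolower(as.character(response)))
  shared <- intersect(names(kw), names(rs))
  n_correct <- if (length(shared)) sum(pmin(kw[shared], rs[shared])) else 0L
  list(n_tokens = length(keywords), n_correct = as.integer(n_correct))
}

#' Read a transcription file
#'
#' Tab-delimited with columns `participant_id`, `trial_id`, `mode`
#' (`phoneme` or `keyword`), `target_tokens`, `response_tokens`; token fields
#' are space-separated.
#'
#' @param path file path.
#' @return data.frame, one row per trial, token fields kept as strings.
#' @export
read_transcriptions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("participant_id", "trial_id", "mode",
                "target_tokens", "response_tokens")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_domain("transcription file misses column(s): %s",
                paste(missing, collapse = ", "))
  bad <- which(!df$mode %in% c("phoneme", "keyword"))
  if (length(bad))
    stop_domain("row %d: mode must be 'phoneme' or 'keyword', got '%s'",
                bad[1], df$mode[bad[1]])
  df
}

#' Score a transcription table into a trial table
#'
#' Applies [score_word()] to `phoneme`-mode rows and
#' [score_sentence_keywords()] to `keyword`-mode rows.
#'
#' @param transcriptions data.frame as returned by [read_transcriptions()].
#' @return trial table data.frame with columns `participant_id`, `trial_id`,
#'   `n_tokens`, `n_correct`.
#' @export
score_transcriptions <- function(transcriptions) {
  split_tokens <- function(x) {
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    toks[nzchar(toks)]
  }
  scored <- lapply(seq_len(nrow(transcriptions)), function(i) {
    row <- transcriptions[i, ]
    tgt <- split_tokens(row$target_tokens)
    rsp <- split_tokens(row$response_tokens)
    s <- if (row$mode == "phoneme") score_word(tgt, rsp)
         else score_sentence_keywords(tgt, rsp)
    data.frame(participant_id = row$participant_id, trial_id = row$trial_id,
               n_tokens = s$n_tokens, n_correct = s$n_correct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, scored)
}
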