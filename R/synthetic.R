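#' Synthetic cohorts of partial-credit recognition data
#'
#' Generates trial tables with the statistical structure the models assume:
#' each participant has a true mean accuracy `mu_p` and intraclass correlation
#' `rho_p`, and every trial count is drawn from the two-stage beta-binomial
#' scheme. Defaults emulate the reference study design: 20 cochlear-implant
#' listeners, 250 three-phoneme word trials each, 36 sentence trials each with
#' 3-6 keywords (about 152 keywords in total), per-participant accuracy
#' spanning roughly 0.3-0.9 and a shared intraclass correlation.
#'
#' @name synthetic_data
NULL

#' Cohort specification
#'
#' @param n_participants number of participants (default 20).
#' @param mu_range length-2 numeric; per-participant `mu_p` are drawn
#'   uniformly over this range (default `c(0.29, 0.92)`, the observed spread
#'   of phoneme accuracy). Ignored when `mu_values` is given.
#' @param mu_values optional explicit vector of `mu_p` (length
#'   `n_participants`).
#' @param rho shared intraclass correlation (scalar, default 0.35 — the group
#'   estimate for CNC words) or a per-participant vector.
#' @param word_trials word trials per participant (default 250).
#' @param phonemes_per_word tokens per word trial (default 3, CNC words).
#' @param sentence_trials sentence trials per participant (default 36; set 0
#'   to generate words only).
#' @param keywords_per_sentence integer vector the per-sentence keyword count
#'   is drawn from, discrete-uniformly (default `3:6`; the study reports only
#'   the 152-keyword total, and 36 x 4.2 ~ 152).
#' @param seed integer master seed for the whole cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20,
                        mu_range = c(0.29, 0.92),
                        mu_values = NULL,
                        rho = 0.35,
                        word_trials = 250,
                        phonemes_per_word = 3,
                        sentence_trials = 36,
                        keywords_per_sentence = 3:6,
                        seed = 1L) {
  if (n_participants < 1) stop_domain("`n_participants` must be >= 1")
  if (is.null(mu_values)) {
    if (length(mu_range) != 2 || mu_range[1] > mu_range[2] ||
        mu_range[1] <= 0 || mu_range[2] >= 1)
      stop_domain("`mu_range` must be an increasing pair inside (0, 1)")
  } else if (length(mu_values) != n_participants) {
    stop_domain("`mu_values` must have length n_participants")
  }
  if (!length(rho) %in% c(1, n_participants))
    stop_domain("`rho` must be a scalar or one value per participant")
  if (any(rho < 0) || any(rho >= 1)) stop_domain("`rho` must lie in [0, 1)")
  structure(list(n_participants = as.integer(n_participants),
                 mu_range = mu_range, mu_values = mu_values, rho = rho,
                 word_trials = as.integer(word_trials),
                 phonemes_per_word = as.integer(phonemes_per_word),
                 sentence_trials = as.integer(sentence_trials),
                 keywords_per_sentence = as.integer(keywords_per_sentence),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw the participant-level ground truth for a cohort
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `participant_id`, `mu_p`, `rho_p`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- spawn_seeds(spec$seed, c("cohort", "trials", "transcripts"))
  mu <- if (is.null(spec$mu_values)) {
    withr::with_seed(seeds[["cohort"]],
                     stats::runif(spec$n_participants,
                                  spec$mu_range[1], spec$mu_range[2]))
  } else spec$mu_values
  if (any(mu <= 0) || any(mu >= 1)) stop_domain("all `mu_p` must lie in (0, 1)")
  rho <- rep(spec$rho, length.out = spec$n_participants)
  data.frame(participant_id = sprintf("P%02d", seq_len(spec$n_participants)),
             mu_p = mu, rho_p = rho, stringsAsFactors = FALSE)
}

# Draw one participant's counts for trials with (possibly varying) n_tokens.
draw_counts <- function(n_tokens, mu, rho) {
  if (rho == 0) return(stats::rbinom(length(n_tokens), n_tokens, mu))
  ab <- mu_rho_to_alpha_beta(mu, rho)
  pi <- stats::rbeta(length(n_tokens), ab$alpha, ab$beta)
  stats::rbinom(length(n_tokens), n_tokens, pi)
}

#' Generate the trial table for a cohort
#'
#' Word trials have `n_tokens = phonemes_per_word`; sentence trials draw their
#' keyword counts from `keywords_per_sentence`. Every count follows the
#' two-stage beta-binomial scheme with that participant's `(mu_p, rho_p)`.
#' Trial ids carry the stimulus type (`word_###` / `sent_###`).
#'
#' @param participants data.frame from [generate_cohort()].
#' @param spec the matching [cohort_spec()].
#' @return trial table data.frame (`participant_id`, `trial_id`, `n_tokens`,
#'   `n_correct`).
#' @export
generate_trials <- function(participants, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- spawn_seeds(spec$seed, c("cohort", "trials", "transcripts"))
  withr::with_seed(seeds[["trials"]], {
    per_participant <- lapply(seq_len(nrow(participants)), function(i) {
      p <- participants[i, ]
      out <- list()
      if (spec$word_trials > 0) {
        nt <- rep(spec$phonemes_per_word, spec$word_trials)
        out$words <- data.frame(
          participant_id = p$participant_id,
          trial_id = sprintf("word_%03d", seq_len(spec$word_trials)),
          n_tokens = nt,
          n_correct = draw_counts(nt, p$mu_p, p$rho_p),
          stringsAsFactors = FALSE)
      }
      if (spec$sentence_trials > 0) {
        nt <- sample(spec$keywords_per_sentence, spec$sentence_trials,
                     replace = TRUE)
        out$sentences <- data.frame(
          participant_id = p$participant_id,
          trial_id = sprintf("sent_%03d", seq_len(spec$sentence_trials)),
          n_tokens = nt,
          n_correct = draw_counts(nt, p$mu_p, p$rho_p),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
    tab <- do.call(rbind, per_participant)
    rownames(tab) <- NULL
    validate_trial_table(tab)
  })
}

#' Generate a whole synthetic dataset (ground truth + trials)
#'
#' @param spec a [cohort_spec()].
#' @return list with `spec`, `participants` (ground truth) and `trials`.
#' @export
generate_dataset <- function(spec) {
  participants <- generate_cohort(spec)
  list(spec = spec, participants = participants,
       trials = generate_trials(participants, spec))
}

#' Fabricate transcription pairs that score back to a trial table
#'
#' For every trial a target token sequence is invented and a response is built
#' that differs from it by exactly `n_tokens - n_correct` substitutions, so
#' that re-scoring the transcriptions reproduces the input counts. This is a
#' round-trip fixture for the scoring stage, not a model of real responses.
#'
#' @param trials trial table data.frame.
#' @param alphabet character vector of at least 2 distinct tokens (default 20
#'   consonant-vowel syllables).
#' @param mode `"phoneme"` (edit-distance scoring) or `"keyword"`.
#' @param seed integer seed.
#' @return transcription data.frame with the schema of
#'   [read_transcriptions()].
#' @export
generate_transcriptions <- function(trials, alphabet = NULL,
                                    mode = c("phoneme", "keyword"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(alphabet))
    alphabet <- paste0(rep(c("b", "d", "g", "k", "m"), each = 4),
                       c("a", "e", "i", "o"))
  alphabet <- unique(as.character(alphabet))
  if (length(alphabet) < 2)
    stop_domain("`alphabet` needs at least 2 distinct tokens to guarantee substitutions differ")
  validate_trial_table(trials)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nrow(trials)), function(i) {
      n <- trials$n_tokens[i]; k <- trials$n_correct[i]
      repeat {
        target <- sample(alphabet, n, replace = TRUE)
        response <- target
        if (k < n) {
          wrong <- sample.int(n, n - k)
          response[wrong] <- vapply(target[wrong], function(tok)
            sample(setdiff(alphabet, tok), 1), character(1))
        }
        s <- if (mode == "phoneme") score_word(target, response)
             else score_sentence_keywords(target, response)
        # substitutions can in principle be undercut by an insert/delete
        # alignment (or keyword collisions); reject and redraw if so
        if (s$n_correct == k) break
      }
      data.frame(participant_id = trials$participant_id[i],
                 trial_id = trials$trial_id[i], mode = mode,
                 target_tokens = paste(target, collapse = " "),
                 response_tokens = paste(response, collapse = " "),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
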