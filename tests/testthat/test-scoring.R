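test_that("edit_distance handles the canonical cases", {
  expect_identical(edit_distance(c("k", "ae", "t"), c("k", "ae", "t")), 0L)
  expect_identical(edit_distance(c("b", "ae", "t"), c("p", "ae", "t")), 1L)
  expect_identical(edit_distance(c("k", "ae", "t"), character(0)), 3L)
  expect_identical(edit_distance(character(0), character(0)), 0L)
  expect_identical(edit_distance(c("a", "b"), c("b", "a")), 2L)
  # multi-character tokens are compared as whole symbols, not characters
  expect_identical(edit_distance(c("dog"), c("d", "o", "g")), 3L)
})

test_that("edit_distance matches adist on random single-char sequences", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      a <- sample(letters[1:4], sample(0:8, 1), replace = TRUE)
      b <- sample(letters[1:4], sample(0:8, 1), replace = TRUE)
      expect_identical(
        edit_distance(a, b),
        as.integer(utils::adist(paste(a, collapse = ""),
                                paste(b, collapse = ""))[1, 1]))
    }
  })
})

test_that("edit_distance is a metric on token sequences", {
  withr::with_seed(7, {
    seqs <- replicate(12, sample(c("p", "b", "ae", "t"), sample(1:6, 1),
                                 replace = TRUE), simplify = FALSE)
    for (i in seq_along(seqs)) {
      for (j in seq_along(seqs)) {
        dij <- edit_distance(seqs[[i]], seqs[[j]])
        expect_identical(dij, edit_distance(seqs[[j]], seqs[[i]]))
        expect_gte(dij, abs(length(seqs[[i]]) - length(seqs[[j]])))
        if (i == j) expect_identical(dij, 0L)
        for (k in seq_along(seqs)) {
          expect_lte(dij, edit_distance(seqs[[i]], seqs[[k]]) +
                       edit_distance(seqs[[k]], seqs[[j]]))
        }
      }
    }
  })
})

test_that("score_word applies the clamped three-minus-edits rule", {
  expect_identical(score_word(c("k", "ae", "t"), c("k", "ae", "t"))$n_correct, 3L)
  expect_identical(score_word(c("b", "ae", "t"), c("p", "ae", "t"))$n_correct, 2L)
  # long unrelated response: clamps at zero, never negative
  s <- score_word(c("k", "ae", "t"), rep(c("z", "u"), 4))
  expect_identical(s$n_correct, 0L)
  expect_identical(s$n_tokens, 3L)
  expect_error(score_word(character(0), c("a")), "non-empty")
})

test_that("adding a substitution error never increases the word score", {
  withr::with_seed(13, {
    alphabet <- c("p", "b", "t", "d", "k", "g")
    for (rep in 1:25) {
      target <- sample(alphabet, 3, replace = TRUE)
      response <- target
      prev <- score_word(target, response)$n_correct
      for (pos in sample(3)) {
        response[pos] <- sample(setdiff(alphabet, target[pos]), 1)
        cur <- score_word(target, response)$n_correct
        expect_lte(cur, prev)
        prev <- cur
      }
    }
  })
})

test_that("keyword scoring counts consumable case-insensitive matches", {
  resp <- c("the", "dog", "ran", "to", "the", "park")
  expect_identical(
    score_sentence_keywords(c("dog", "ran", "park"), resp)$n_correct, 3L)
  expect_identical(
    score_sentence_keywords(c("dog", "ran", "park"), c("a", "cat", "sat"))$n_correct, 0L)
  # consumption: one response token cannot satisfy two identical keywords
  expect_identical(
    score_sentence_keywords(c("dog", "dog"), c("one", "dog"))$n_correct, 1L)
  expect_identical(
    score_sentence_keywords(c("Dog", "Park"), c("dog", "PARK"))$n_correct, 2L)
  expect_error(score_sentence_keywords(character(0), c("a")), "non-empty")
})

test_that("scored outputs always satisfy the trial-record invariants", {
  withr::with_seed(3, {
    for (rep in 1:40) {
      target <- sample(letters[1:5], sample(1:6, 1), replace = TRUE)
      response <- sample(letters[1:6], sample(0:8, 1), replace = TRUE)
      w <- score_word(target, response)
      expect_true(w$n_correct >= 0 && w$n_correct <= w$n_tokens)
      k <- score_sentence_keywords(target, response)
      expect_true(k$n_correct >= 0 && k$n_correct <= k$n_tokens)
    }
  })
})

test_that("transcription files round-trip through read + score", {
  tab <- data.frame(
    participant_id = c("P1", "P1", "P2"),
    trial_id = c("word_001", "sent_001", "word_001"),
    mode = c("phoneme", "keyword", "phoneme"),
    target_tokens = c("k ae t", "dog ran park", "b ae t"),
    response_tokens = c("k ae t", "the dog ran home", "p ae d"),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  scored <- score_transcriptions(read_transcriptions(path))
  expect_identical(scored$n_correct, c(3L, 2L, 1L))
  expect_identical(scored$n_tokens, c(3L, 3L, 3L))

  bad <- tab; bad$mode[2] <- "syllable"
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_transcriptions(path), "row 2")
})
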