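# partialcredit

Beta-binomial analysis of partial-credit speech recognition scoring.

## The problem

Speech recognition tests (word lists, sentence sets) are scored either by
whole items — the word was right or wrong — or by *partial credit*: the
number of phonemes correct in a word, or keywords correct in a sentence.
Partial credit promises more information per trial, but meaningful speech
carries context: if a listener recovers part of a word or sentence, the
remaining tokens become easier to infer. Token outcomes within a trial are
therefore **correlated**, and the extra information per trial is smaller
than the token count suggests.

`partialcredit` is for hearing researchers and clinician-scientists who want
to (a) quantify that within-trial correlation from trial-level count data,
(b) decide formally whether it is needed to explain their data, and (c)
plan list lengths that achieve a target measurement precision under it.

## The model

For trial *t* of participant *p*, the count of correct tokens is

```
X_tp ~ BetaBinomial(n_t, mu_p, rho_p)
```

parameterized by the mean per-token accuracy `mu = alpha / (alpha + beta)`
and the intraclass correlation `rho = 1 / (alpha + beta + 1)` of the
underlying `Beta(alpha, beta)` draw. `rho = 0` is the binomial
(context-free) limit; as `rho -> 1` recognition becomes all-or-nothing. The
count variance is the binomial variance times the design effect
`1 + (n - 1) rho`, so the standard error of mean accuracy from a `W`-word
list with `n` tokens per word is

```
SD(mean accuracy) = sqrt( mu (1 - mu) (1 + (n - 1) rho) / (n W) ).
```

Four nested models are fit by MAP optimization and adaptive random-walk
Metropolis under `Beta(2, 2)` priors on every `mu` and `rho`:

| model | distribution | accuracy | correlation |
|---|---|---|---|
| `binomial` | Binomial | per participant | — |
| `bb-individual` | BetaBinomial | per participant | per participant |
| `bb-shared` | BetaBinomial | per participant | shared |
| `bb-pooled` | BetaBinomial | shared | shared |

Models are compared by PSIS-LOO (self-contained implementation, including
the generalized-Pareto tail smoothing and per-trial Pareto-k diagnostics):
a model is declared better only when its ELPD advantage exceeds 4 and the
paired standard error of the difference is smaller than the advantage.

## Worked example

Simulate a study-shaped cohort (20 participants, 250 three-phoneme words
each, accuracy spanning 0.29–0.92, shared `rho = 0.35`), fit the shared-
correlation model, compare it with the binomial model, and plan list
lengths:

```r
library(partialcredit)

ds    <- generate_dataset(cohort_spec(n_participants = 20, rho = 0.35, seed = 42))
words <- ds$trials[grepl("^word_", ds$trials$trial_id), ]

fit <- fit_posterior(model_spec("bb-shared"), words, seed = 7)
fit
#> partialcredit posterior fit: model 'bb-shared'
#>   6000 retained draws (4 chains), 21 parameters
#>   max Rhat 1.008, min ESS 899

s <- summary(fit)
s[s$parameter %in% c("mu[P01]", "mu[P02]", "rho_group"), 1:7]
#>  parameter    map   mean     sd   q2.5  q97.5   rhat
#>    mu[P01] 0.5579 0.5582 0.0250 0.5073 0.6058 1.0018
#>    mu[P02] 0.4411 0.4409 0.0228 0.3990 0.4868 1.0030
#>  rho_group 0.3567 0.3578 0.0103 0.3373 0.3787 1.0037

bin <- fit_posterior(model_spec("binomial"), words, seed = 7)
compare_models(list(`bb-shared` = elpd_loo(fit), binomial = elpd_loo(bin)))
#>       model elpd_loo elpd_se  p_loo p_loo_se delta_elpd delta_se decision
#> 1 bb-shared  -5939.7  42.834 21.010  0.30278       0.00    0.000     best
#> 2  binomial  -6686.7  63.079 34.271  0.73380    -746.99   41.586    worse

precision_analysis(seed = 1)
#> Precision of phoneme vs whole-word scoring (mu = 0.50, rho = 0.35)
#>   reference: whole-word SD at 50 words = 0.0707 (simulated 0.0707)
#>   minimum phoneme-scored words: 29 simulated, 29 analytic
```

Reading the output: the generating truth for participants P01/P02 was
`mu_p = 0.584 / 0.443` and the shared correlation 0.35 — the fit recovers
them within a couple of standard errors, and `p_loo ≈ 21` matches the
model's 21 parameters. The comparison declares the binomial model decisively
worse (`ΔELPD ≈ -747`, SE ≈ 42): within-trial correlation is needed to
explain the counts. The precision analysis says that with `rho = 0.35`,
about 29–30 phoneme-scored words match the precision of a 50-word
whole-word list — not the 17 words that naive independent-phoneme scaling
(50/3) would promise.

Scoring raw transcriptions (phoneme tokens by Levenshtein edit distance,
keywords by consumable exact match) and a subcommand CLI are included:

```sh
Rscript -e 'partialcredit::pc_cli()' run-all --seed 1 --outdir run1
Rscript -e 'partialcredit::pc_cli()' precision --draws 10000 --outdir prec
```

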