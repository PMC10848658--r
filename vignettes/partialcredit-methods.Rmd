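---
title: "Models and methods behind partialcredit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind partialcredit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A speech recognition test presents a listener with stimuli — words made of
phonemes, sentences containing keywords — and records, per trial, how many
of the $n_t$ tokens were correctly identified. Whole-item scoring keeps one
bit per trial; partial-credit scoring keeps the count $X_{tp} \in
\{0,\dots,n_t\}$. If token outcomes were independent, a three-phoneme word
would carry three times the information of a whole-word judgement. They are
not independent: context lets listeners infer tokens they did not hear, so
outcomes within a trial are positively correlated and partially redundant.

## The beta-binomial model

We model the per-trial recognition probability as a latent draw
$\pi_{tp} \sim \mathrm{Beta}(\alpha_p, \beta_p)$ followed by
$X_{tp} \sim \mathrm{Binomial}(n_t, \pi_{tp})$. Instead of
$(\alpha, \beta)$ the package works throughout in the interpretable pair

$$\mu = \frac{\alpha}{\alpha+\beta}, \qquad
  \rho = \frac{1}{\alpha+\beta+1},$$

the mean per-token accuracy and the intraclass correlation of token
outcomes within a trial. The count mean is $n\mu$, independent of $\rho$,
and the variance is $n\mu(1-\mu)\,[1+(n-1)\rho]$: the binomial variance
inflated by the familiar design effect. $\rho = 0$ *is* the binomial model
(a legal parameter value for the pmf, moments and sampler, though it has no
$(\alpha,\beta)$ representation and the conversion map rejects it);
$\rho \to 1$ gives U-shaped, all-or-nothing recognition.

Numerics: the pmf is evaluated in log space as $\log\binom{n}{k} + \log
B(k+\alpha, n-k+\beta) - \log B(\alpha,\beta)$. For $\rho \lesssim 10^{-8}$
the difference of log-gamma terms of size $O(1/\rho)$ cancels
catastrophically — it can even produce "log-probabilities" above zero,
which during development sent the optimizer chasing $\rho \to 0$ — so below
that threshold the code uses the binomial limit, whose true distance from
the beta-binomial is below $n^2\rho \approx 10^{-6}$, smaller than the
cancellation error it replaces. Sampling is the two-stage compositional
scheme (one fresh $\pi$ per trial, then a binomial draw), which mirrors the
generative story and keeps the latent $\pi$ available for diagnostics.

## Scoring transcribed responses

Word responses are scored by unit-cost Levenshtein distance between token
sequences: phonemes correct $= \max(0,\ n - d_\mathrm{edit})$. The paper
trail for this rule specifies only "edit distance"; unit costs are the
standard reading, and under unit costs the direction of transformation is
symmetric. Sentence responses are scored by keywords present in the
response, case-insensitively, with each response token consumable once —
the official scoring criteria shipped with the sentence materials are not
public, so exact matching is a documented simplification. Token alphabets
are opaque strings; any transcription scheme works.

## Synthetic cohorts

The generator's defaults emulate the reference study design: 20
participants, 250 three-phoneme word trials each, 36 sentence trials each
with keyword counts drawn uniformly from $\{3,4,5,6\}$ (the study reports
only the 152-keyword total; $36 \times 4.2 \approx 152$, and the mean of
this choice, 4.5, puts each participant near that total), per-participant
accuracy drawn uniformly on $(0.29, 0.92)$ — the observed range of phoneme
accuracy — and a shared intraclass correlation of 0.35, the group estimate
for word materials. Accuracies are drawn uniformly rather than from a
hyperprior because the analysis models participants independently; no
population distribution is asserted. Ground truth is always returned
alongside the trial table so recovery is testable.

What the generator does *not* emulate: lexical and acoustic properties of
particular words, list effects, learning or fatigue across the fixed
presentation order, and any dependence of $\rho$ on accuracy. A green
parameter-recovery test therefore establishes that the estimator works on
data obeying the model, not that real listeners obey it.

Fabricated transcription pairs (for round-trip tests of the scoring stage)
place exactly $n-k$ substitutions into an invented target. A substitution
pattern can occasionally be undercut by an insert/delete alignment, so the
construction verifies its own score and redraws until exact — a guarantee
by construction, not by hope.

## Inference

All four models put independent $\mathrm{Beta}(2,2)$ priors on every $\mu$
and $\rho$: weakly informative, vanishing at the boundaries, and
overridable (`prior_shape`), which the tests use to confirm that a uniform
prior moves estimates by less than 0.02 on the default cohort.

**MAP.** "Most likely values" are posterior modes in the constrained
$(\mu,\rho)$ coordinates — the convention under which the conjugate
binomial case gives the textbook $(s+1)/(N+2)$ — found by BFGS on a logit
transform from multiple starts (one empirical-proportion start plus random
restarts; best value wins, ties to the earliest start). The optimizer
objective deliberately omits the logit Jacobian; the MCMC target includes
it.

**Sampling.** Chains are adaptive random-walk Metropolis on the logit
scale, initialized by jittering the MAP. Because participants are
conditionally independent given shared parameters, all per-participant
parameters are proposed simultaneously and accepted element-wise (one
vectorized likelihood evaluation per block per iteration); shared group
parameters are scalar updates against the full likelihood. Proposal scales
adapt toward ~0.3 acceptance during warmup (Robbins–Monro, frozen
afterwards). Trial tables are aggregated to unique (participant, $n$, $k$)
cells first, which makes a 5000-trial likelihood evaluation the cost of a
few dozen `lbeta` calls. Defaults — 4 chains × 2500 iterations, 1000
warmup — give split-$\hat R < 1.01$ and effective sample sizes above 400 on
the default cohort; $\hat R \ge 1.05$ on any parameter marks the fit as
failed (it is still returned, with diagnostics). $\rho$ is capped at
$1-10^{-6}$ on the unconstrained scale. Identical seed and configuration
reproduce draws bit-for-bit; every random stage in the package takes an
explicit seed and restores the caller's RNG state.

## Model comparison

PSIS-LOO is implemented from scratch. Per trial, importance ratios are the
reciprocal pointwise likelihoods over retained draws; the largest
$M = \lceil \min(0.2S,\ 3\sqrt S\,) \rceil$ ratios are replaced by expected
order statistics of a generalized Pareto distribution fitted to their
exceedances (Zhang–Stephens-style quasi-Bayesian profile estimator — a
grid over the inverse scale weighted by profile likelihood), capped at the
raw maximum. Tails shorter than 5 points fall back to plain truncation
with the shape reported as not estimable; $k > 0.7$ flags a trial as
unreliable (warning, not failure — accepted reliability guidance, since
the source analysis states no threshold). Trials of one participant with
identical counts have identical likelihood columns, so LOO is computed
once per unique column and replicated — an exact shortcut, verified
against column-by-column computation in the tests.

Comparison uses paired pointwise differences: $\mathrm{SE}(\Delta) =
\sqrt{T\,\mathrm{var}(\mathrm{elpd}_{i,A} - \mathrm{elpd}_{i,B})}$, and a
model is declared decisively better only when $|\Delta\mathrm{ELPD}| > 4$
and $\mathrm{SE}(\Delta) < |\Delta|$. The tests validate PSIS-LOO against
*exact* leave-one-out refits, available in closed form for the binomial
model because the Beta prior is conjugate — the refit posterior with trial
$i$ removed is again Beta, so $\log p(y_i \mid y_{-i})$ is a beta-binomial
predictive.

## Precision planning

With the design effect in hand, the standard deviation of mean accuracy
over a $W$-word list is $\sqrt{\mu(1-\mu)(1+(n-1)\rho)/(nW)}$. The package
reports both this closed form and a Monte-Carlo version (10 000 replicate
lists per grid point over 10–100 words, by default at $\mu = 0.5$, where
binomial uncertainty peaks). "Matching" a reference precision is
operationalized as the first crossing — the smallest integer $W$ whose SD
does not exceed the reference (whole-word scoring of 50 words, the common
clinical list). Near the crossing the Monte-Carlo curve wobbles by design
(about 1% relative SD at 10 000 draws), so simulated and analytic minima
can differ by one word; both are always reported and a flag marks
disagreement. At $\rho = 0$ the analytic minimum is exactly
$\lceil 50/3 \rceil = 17$ words; at $\rho = 0.35$ the analytic crossing is
29 and the simulation typically reports 29–30.

## Pipeline and reproducibility

`run_pipeline()` (and the `pc_cli()` subcommands `simulate`, `score`,
`fit`, `compare`, `precision`, `run-all`) compose the stages. One master
seed deterministically spawns per-stage seeds (`sample.int` under the
master seed), so any stage can be rerun alone and the whole run is
bit-reproducible; every artifact carries the seed and a hash of the full
config. Config files are JSON, or YAML when the `yaml` package is present
(JSON is the guaranteed path because `yaml` is an optional dependency).
By default the pipeline simulates the full study-shaped dataset but fits
and compares models on the word trials (`fit_subset = "words"`), mirroring
an analysis that treats stimulus sets separately; set it to `"sentences"`
or `"all"` to change that.

## Known limitations

- Within-trial correlation is exchangeable: every token pair in a trial
  shares one $\rho$. Serial position effects and token-specific difficulty
  are out of scope.
- The sampler is gradient-free by design (targets have at most ~40
  parameters); it is not a general-purpose replacement for HMC on larger
  models.
- Per-participant $\mu$ estimates from 250 three-phoneme words carry a
  standard error of roughly $\sqrt{\mu(1-\mu)\cdot 1.7/750} \approx 0.024$
  at $\rho = 0.35$; requiring *every* participant in a 20-person cohort to
  land within ±0.06 (2.5 SE) of truth fails for at least one participant
  in roughly one cohort in eight. Joint coverage bands over many
  participants must be wider than per-participant intuition suggests.
- Keyword scoring is exact matching; homophones and accepted-variant rules
  in published sentence materials are not modeled.
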