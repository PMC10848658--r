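Package: partialcredit
Title: Beta-Binomial Analysis of Partial-Credit Speech Recognition Scoring
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing partial-credit (phoneme- or keyword-level)
    speech recognition scores with beta-binomial models. Provides exact
    beta-binomial distribution machinery in the mean/intraclass-correlation
    (mu, rho) parameterization, edit-distance scoring of transcribed
    responses, synthetic cohort generation, Bayesian estimation (MAP and
    adaptive Metropolis posterior sampling under Beta(2,2) priors) of four
    binomial/beta-binomial models with shared or per-participant parameters,
    self-contained PSIS-LOO model comparison, and measurement-precision
    simulation quantifying how intraclass correlation erodes the benefit of
    partial-credit scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    matrixStats,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
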