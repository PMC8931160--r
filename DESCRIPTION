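Package: coged
Title: Cognitive Effort Discounting: Simulation, Scoring and Bayesian Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for cognitive effort discounting (COG-ED) studies run in two
    cognitive domains (N-back working memory and speech-in-noise comprehension).
    Simulates cohorts with a latent domain-general motivation trait, runs the
    stepwise titration staircase that yields indifference points, converts
    indifference points to subjective values on the 0-2 scale, fits
    random-intercept mixed models of subjective value and workload ratings,
    computes Bayesian (partial) correlations and paired-contrast Bayes factors
    by exact grid integration, and performs sequential Bayes-factor design
    analysis with evidence boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
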