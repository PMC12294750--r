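Package: infosim
Title: Simulation-Based Diagnostics for Informativity Effects on Word Duration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for asking whether an apparent effect of word informativity
    on articulatory reduction (operationalized as log word duration) could be a
    predictability effect in disguise, i.e. an artifact of sampling noise in
    bigram conditional-probability estimates. Provides maximum-likelihood
    bigram statistics (per-token predictability, per-word informativity,
    context frequency), a closed-form adaptive partial-pooling estimator,
    ordinary least squares and random-intercept mixed duration regressions
    with Satterthwaite p-values and marginal/conditional R-squared, a
    parametric-bootstrap null simulator in which durations are driven by true
    predictability only while predictors are re-estimated from each resampled
    corpus, false-alarm and Monte-Carlo diagnostics over the resulting
    coefficient distributions, and a Zipfian synthetic-corpus generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
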