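Package: speedacc
Title: Accumulator-Model Analysis of Speed-Accuracy Tradeoff Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing cued two-choice response-time experiments in
    which instructions trade speed against accuracy. Provides trial-level data
    handling (validation, exclusions, defective RT quantiles, vincentized group
    summaries), Wiener diffusion first-passage densities with chi-square
    quantile fitting of the drift diffusion model, linear ballistic accumulator
    defective densities with maximum-likelihood fitting, frequentist and
    default Bayesian t-tests (JZS Cauchy prior, posterior probability of the
    null), repeated-measures ANOVA helpers, a seeded synthetic-study generator
    with deadline censoring, and an end-to-end behavioural analysis pipeline
    with parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
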