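Package: lbachoice
Title: Linear Ballistic Accumulator Modeling of Explicit Risky Choice
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a four-gamble explicit risky-choice task, fits
    drift-rate and response-boundary variants of the linear ballistic
    accumulator (LBA) to trial-level choices and reaction times by maximum
    likelihood, predicts per-pair choice probabilities (including on held-out
    trials), and assesses fit with quantile-probability tables, chi-square
    and Kolmogorov-Smirnov goodness of fit. Includes behavioral measures of
    utility-curve concavity, risk seeking, and counterfactual sensitivity,
    plus a synthetic-cohort generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
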