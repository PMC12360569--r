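Package: pvsignals
Title: Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal screening in spontaneous
    adverse-event reporting databases laid out as four linked tables
    (demographics, drug exposures, reactions, medical history). Implements
    reporting odds ratios and the Bayesian confidence propagation neural
    network information component for adverse-event signals; the omega
    shrinkage measure, additive, multiplicative and chi-square statistics
    for drug-drug interaction screening with a two-of-four composite rule;
    multivariable logistic regression for case-level predictors;
    time-to-onset and outcome summaries; and a configurable simulator of
    spontaneous reports with planted drug effects and interactions for
    validating each stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
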