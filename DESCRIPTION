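Package: genolcm
Title: Latent Class Accuracy Models for Categorical Tests Without a Gold Standard
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the accuracy of multiple categorical laboratory tests
    when no gold-standard reference exists, using latent class models in the
    Hui-Walter tradition fitted by the EM algorithm. Supports three-category
    genotype panels (e.g. the p53 codon 72 Arg/Pro polymorphism typed by
    several laboratory methods), missing calls, equal-accuracy and
    outcome-stratified accuracy constraints, pairwise conditional-dependence
    terms, and likelihood ratio tests between nested models. A companion
    outcome model links the latent genotype to a binary disease outcome and
    reports misclassification-corrected risks and odds ratios; empirical
    (error-ignoring) prevalences and odds ratios, crude agreement and
    Cicchetti-Allison weighted kappa statistics are provided for comparison.
    Includes a synthetic-data generator that emulates the assumed
    data-generating process for simulation studies and parameter-recovery
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
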