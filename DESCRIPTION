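Package: vhsl
Title: Visuo-Haptic Statistical Learning: Designs, Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-modality statistical-learning experiments in which
    objects are defined purely by co-occurrence statistics of abstract shape
    pairs, experienced either visually or through haptic pulling. The package
    enumerates the full combinatorial stimulus sets (grid scenes built from
    horizontal and vertical shape pairs), computes breakage forces from a
    bond model, generates every phase design (exposure, training, pulling
    test, two-alternative familiarity test), simulates behavioral cohorts
    with a known latent learning strength, and implements the accompanying
    analyses: per-participant performance measures, a rectified
    exponential-binomial model linking familiarity accuracy to pulling
    correlation (maximum-likelihood fit, likelihood-ratio test,
    profile-likelihood confidence bands, Laplace-approximation Bayes
    factor), a within-participant object-consistency statistic, an
    explicitness partial-correlation analysis, and scaled JZS Bayes factors
    for t-tests and regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
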