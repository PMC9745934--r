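Package: metafew
Title: Beta-Binomial and Standard Meta-Analysis Methods for Very Few Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood beta-binomial meta-analysis models for binary
    outcomes (the common-rho model, its random-treatment-effect extension, and
    two common-beta variants), Laplace-approximated logistic mixed models, and
    the classical inverse-variance, Mantel-Haenszel, Peto and collapsed-table
    estimators, together with a simulation engine that emulates realistic
    Cochrane-style meta-analytic data situations (log-normal study sizes,
    beta-distributed control risks, Fleishman-transformed heterogeneity and
    effect sizes) and a performance harness computing convergence counts, bias,
    coverage, confidence-interval length and power. Designed for studying and
    comparing meta-analytic methods when only two to ten studies are available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    lme4,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
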