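Package: propower
Title: Power and Type I Error of Analysis Methods for Single-Item Longitudinal Ordinal Patient-Reported Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework comparing analysis methods for single-item
    longitudinal ordinal patient-reported outcome (PRO-CTCAE-style) data in
    two-arm trials. Generates correlated ordinal panels from a Gaussian copula
    with multinomial marginals; computes per-patient toxicity summaries
    (toxicity index, average, maximum) under post-baseline and
    baseline-adjusted strategies; fits probabilistic index models by pairwise
    estimating equations with sandwich variance; fits cumulative logit mixed
    models with a random patient intercept by maximum likelihood with Laplace
    approximation, tested by chi-square and parametric-bootstrap likelihood
    ratio tests; and orchestrates replicate studies reporting type I error and
    power with 1-ECDF summaries and paired-t method contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    statmod,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
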