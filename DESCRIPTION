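Package: vonfrey
Title: Simulation and Signal-Detection Analysis of von Frey Tactile Threshold Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for method-of-limits tactile detection experiments with von
    Frey filaments analysed through signal detection theory. Provides a
    simulator of equal-variance Gaussian observers running the four-block
    ascending/descending staircase protocol with catch trials, corrected
    hit/false-alarm rates with the parametric sensitivity index Az and response
    criterion c, robust group statistics (Cliff's delta with consistent-variance
    confidence intervals, Spearman correlations, Zou's interval for comparing
    independent correlations, ICC(3,k)), and a cumulative probability model
    (proportional-odds regression for continuous outcomes) with likelihood-ratio
    and Wald inference, Nagelkerke R2, and best-subset selection by BIC with BIC
    weights and approximate Bayes factors. Includes an end-to-end pipeline that
    simulates cohorts, scores sessions, and tests whether a conservative
    response criterion (rather than reduced sensitivity) drives elevated
    thresholds.
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
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
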