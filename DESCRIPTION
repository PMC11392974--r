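Package: dynoccu
Title: Bayesian Multi-Season Occupancy Models for Camera-Trap Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds detection histories from camera-trap event streams
    (independent-event filtering, five-day occasion discretization, effort
    accounting), fits Bayesian dynamic (multi-season) occupancy models with
    logit-linked covariates on first-season occupancy, colonization,
    extinction and detection, compares candidate models by Pareto-smoothed
    importance-sampling leave-one-out cross-validation (PSIS-LOO), averages
    them by stacking of predictive distributions, and derives seasonal
    occupancy trajectories. Includes a synthetic-data generator emulating a
    seasonal mesocarnivore camera-trapping design so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
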