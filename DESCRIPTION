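Package: coxewas
Title: Environment-Wide Association Scans of Dietary Exposures with
    Time-Varying Cox Models and a Permutation False Discovery Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An environment-wide association study (EWAS) toolkit for
    longitudinal nutritional epidemiology. Converts repeated food frequency
    questionnaire (FFQ) responses into cumulative-average food and nutrient
    exposures, screens every exposure against an incident disease endpoint
    with extended (time-varying) Cox proportional-hazards models, controls
    multiple testing with a confounder-preserving permutation false
    discovery rate in which case labels are re-drawn as a biased sample
    weighted by covariate-predicted risk, and decomposes nutrient-level
    hazard ratios over a bipartite food-nutrient network as weighted
    geometric means of food hazard ratios. Includes a synthetic longitudinal
    cohort generator with known ground truth so the whole pipeline is
    testable without access to restricted cohort data.
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
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
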