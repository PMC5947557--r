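Package: sociocc
Title: Integrated Socioecological Occupancy and Sensitive-Behaviour Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing drivers of carnivore decline in
    human-dominated landscapes by combining ecological and social data
    collected at a matched spatial scale. Implements multiseason (dynamic)
    occupancy models with imperfect detection via a two-state hidden-Markov
    forward recursion, staged forward AIC model selection over candidate
    covariate structures, parametric-bootstrap goodness-of-fit on
    detection-history frequencies, prevalence estimation and logistic
    regression for forced-response randomised-response-technique (RRT)
    questionnaire data, Moran's I screening for spatial autocorrelation
    with a fixed distance band, and a synthetic-data generator that
    emulates a camera-trap plus household-questionnaire study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
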