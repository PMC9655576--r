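Package: trophsim
Title: Agent-Based Simulation of Trophallactic Food-Exchange Networks in Ant Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the intranidal dissemination of food through
    mouth-to-mouth (trophallactic) exchanges in an ant colony. Agents leave
    the nest, feed at an unlimited source and exchange food with nestmates
    with crop-load-dependent probabilities following Hill-type response
    functions. The package supports one-caste and two-emergent-caste
    behavioural regimes, delta/uniform/exponential interindividual trait
    heterogeneity and a power-law distribution of nest-leaving
    probabilities. It includes an observation model (minute-resolution scan
    sampling with a minimum-duration threshold), a synthetic
    experimental-data generator, weighted directed network metrics
    (efficiency, closeness, betweenness, clustering), inequality measures
    (Lorenz curve, Gini coefficient), food-flow dynamics (T50), summary
    statistics, grid-search calibration of giving/receiving probabilities,
    and Kolmogorov-Smirnov / Mann-Whitney / Z-test protocols for comparing
    simulated ensembles with experimental event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    igraph,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
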