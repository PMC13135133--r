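Package: pinnet
Title: Multi-Scale Spatial Association Networks from Point-Intercept Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers pairwise plant spatial associations (aggregation and
    segregation) from point-intercept vegetation surveys. Per-plot one-tailed
    hypergeometric exact tests of co-location are combined across plots with a
    gamma approximation of the exact stratified discrete null (with an exact
    convolution reference), screened with a detectability pre-filter and
    discrete false-discovery-rate control, and assembled into a signed
    regional association network. Network roles are found with a Bernoulli
    stochastic block model and related to functional traits (PCA, pairwise
    PERMANOVA, functional distinctiveness and scarcity) and abiotic context
    (quasi-Poisson models with hierarchical variance partitioning). A
    synthetic-data generator with planted structure makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
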