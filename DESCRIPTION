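Package: wolfselect
Title: Elitist Binary Wolf Search for Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional classification
    data (gene-expression style matrices with few samples and thousands of
    features) using the Elitist Binary Wolf Search Algorithm: a binary wolf
    search metaheuristic with an elitist weight economy that rescales each
    wolf's step size by its share of a conserved unit resource, a bounded
    first-in-first-out memory of worst positions, and elimination/rebirth of
    starved wolves.  Candidate feature subsets are scored by an extreme
    learning machine trained with minimum-norm least squares under stratified
    cross-validation.  Includes plain binary wolf search, binary particle
    swarm optimisation and continuous particle swarm optimisation baselines
    sharing the same fitness contract, classification metrics (accuracy,
    Cohen's kappa, precision, recall, dimension percentage), a synthetic
    high-dimensional data generator with known informative features, readers
    for CSV/TSV, ARFF and libsvm data, and tidy/broom-style accessors with
    ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
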