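Package: wmnet
Title: Weighted White-Matter Connectome Construction and Graph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted structural brain networks from tractography-derived
    fiber-number and fractional-anisotropy matrices over a 90-region anatomical
    parcellation, computes global and nodal graph metrics (clustering
    coefficient, characteristic path length, global and local efficiency,
    betweenness centrality), normalizes small-world parameters against
    degree-preserving random networks, identifies betweenness hubs, and runs
    group-difference and covariate-adjusted correlation statistics across
    normal-control, subjective-cognitive-decline, and amnestic mild-cognitive-
    impairment cohorts. Includes a synthetic three-group connectome cohort
    generator with planted, graded network disruption for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
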