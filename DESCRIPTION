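Package: recallnet
Title: Hierarchical Structural Connectome Analysis of Free-Recall Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links episodic memory performance (picture free recall) to
    properties of the structural brain connectome. Provides population-level
    spurious-edge filtering for weighted connectivity matrices, weighted
    graph metrics (network cost, nodal degree, clustering, path length,
    efficiency, betweenness) with cost-integrated variants over a density
    grid, a hierarchical global-to-nodal-to-edge FDR inference cascade,
    network-based-statistic permutation inference with family-wise error
    control, robust bisquare multi-edge regression, a grey-matter volumetry
    control analysis, and a calibrated synthetic cohort generator so the
    whole pipeline is testable without access to subject-level imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
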