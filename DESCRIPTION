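Package: connectoclust
Title: Constrained Modularity Clustering and Cartography of Directed
    Weighted Connectomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Community detection for directed, weighted neuronal wiring
    diagrams. Implements modularity maximization by simulated annealing
    with bilateral-pair co-membership constraints, two-level hierarchical
    cluster agglomeration, out-strength-preserving null models, partition
    comparison by variation of information with a bootstrap concordance
    test, functional cartography (within-module weight, participation
    coefficient, role classes), compositional diversity (index of
    qualitative variation), and cluster-level information-flow statistics
    (in/out ratios, hub and authority scores, spatial density profiles).
    Ships a planted-partition generator for directed weighted networks
    with bilateral pairs so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
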