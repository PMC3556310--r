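Package: fluxshred
Title: Flux-Weighted Shortest Retroactive Distance Modularity for Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Modularity analysis of reaction-centric metabolic networks using
    Shortest Retroactive Distances (ShReD), the length of the shortest cyclical
    interaction between two reactions. Edge distances may be uniform, weighted
    by metabolic flux (the inverse share of an intermediary metabolite's
    production drawn by the consuming reaction), or weighted by metabolite
    consumer degree. Provides a rank-based log-odds modularity matrix, genetic
    algorithm and exhaustive maximization of the modularity score, recursive
    cycle-preserving bipartitioning into a hierarchical module tree, module
    homogeneity indices, pair partition scores, robust-pair detection across
    metabolic states, and normalized H-V distances between states. Includes
    constrained least-squares flux estimation from measured exchange rates and
    generators for steady-state-consistent synthetic networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    e1071,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
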