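Package: motifmodules
Title: Topological Modules from Multi-Layer Molecular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes multi-layer molecular interaction networks
    (directed regulatory layers such as TF-target and miRNA-mRNA edges,
    undirected layers such as protein-protein, co-functional and homology
    edges) into typed two- and three-node composite subgraphs, clusters
    the subgraphs into small topological modules by maximising the
    edge-to-node ratio on the subgraph hypergraph, and characterises the
    modules in their network context: module-module connectivity
    statistics against sampling nulls, regulator-module links, Gene
    Ontology over-representation, expression-based co-expression,
    differential-correlation and activity scores, Cytoscape export, and
    an edge-resampling stability harness. Includes a synthetic-network
    generator with planted modules for end-to-end validation.
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
    parallel,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
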