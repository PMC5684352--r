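Package: costructure
Title: Co-Structure Analysis of Two-Layer Bipartite Ecological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to disentangle the co-structure of two bipartite
    interaction networks that share both species sets (e.g. a larval
    herbivory layer and an adult flower-visitation layer of the same
    Lepidoptera-plant assemblage). Implements the paired-degree
    contingency analysis (chi-squared test of degree co-distribution
    with Pearson-residual mosaic output), leading-eigenvector
    modularity detection on each layer, the normalized mutual
    information of the two module classifications, and a
    degree-preserving (curveball) configuration-model null that turns
    the observed similarity into an empirical permutation test.
    Includes seeded generators of planted-module bipartite layer pairs
    for benchmarking, readers and writers for edge-list and incidence
    formats, and GraphML export of the module co-structure graph.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
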