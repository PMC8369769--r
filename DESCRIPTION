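Package: bmgedit
Title: Best Match Graph Editing with Triple-Based and Partition-Based Heuristics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with best match graphs (BMGs), the colored
    digraphs that arise in phylogenomics when every gene points to its
    evolutionarily closest relatives in each other species.  Provides rooted
    phylogenetic tree utilities (restriction, rooted triples, the BUILD
    supertree algorithm), construction and recognition of BMGs and
    binary-explainable BMGs, the unsatisfiable-relation (UR) cost of a vertex
    partition, a family of partitioning heuristics (minimum edge cut, Karger
    contraction, greedy and gradient-walk bipartitioning, and two Louvain
    variants), consistent top-down editing heuristics that repair a noisy
    digraph into a valid BMG together with an explaining tree, a simulator for
    randomly perturbed BMG benchmark instances, and arc-set comparison
    metrics with a reproducible benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
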