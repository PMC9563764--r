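Package: ctpa
Title: Crosstalk-Based Pathway Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pathway enrichment analysis that accounts for crosstalk between
    pathways. Gene-level differential-expression scores, combining fold
    change and P-value, are propagated over a global pathway crosstalk map
    (a merged undirected gene network built from pathway interactions,
    protein-protein interactions and transcription-factor regulations)
    using a multi-seed random walk with restart. Pathways are scored by the
    mean propagated risk of their member genes, significance is assessed by
    gene-label permutation with generalized-Pareto refinement of tail
    P-values, and redundancy among significant pathways is reduced by
    Markov clustering of a Jaccard similarity network. Includes a synthetic
    data generator (scale-free networks, overlapping gene sets,
    planted-signal expression profiles) so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
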