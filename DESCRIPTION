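Package: regsign
Title: Sign-Consistency Inference and Enrichment Analysis for MicroRNA
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing signed, directed gene regulatory networks
    downstream of a microRNA, built around the miR-96 / diminuendo inner-ear
    system. Implements tiered-evidence prediction of up/down misregulation
    states on literature-curated networks with consistency checking and edge
    pruning; exact tie-aware Wilcoxon rank-sum statistics and 2^-ddCt relative
    expression for littermate-paired qRT-PCR with QC filtering and
    Benjamini-Hochberg adjustment; ranked hypergeometric heptamer-enrichment
    landscapes over 3'UTR sequences with microRNA seed-match scanning;
    evidence-tiered gene-list compilation and hypergeometric
    over-representation analysis; and protein-protein interaction network
    centrality summaries. A seeded synthetic-data generator provides signed
    networks with planted states, ranked UTR sets with planted seed words, and
    paired Ct tables for fully reproducible testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Biostrings,
    BiocGenerics
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
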