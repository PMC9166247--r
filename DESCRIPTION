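Package: lncnet
Title: LncRNA-mRNA Co-Expression Network Analysis for Pulmonary Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of hub long non-coding RNAs in idiopathic pulmonary
    fibrosis (IPF) from expression profiles: probe-to-gene collapsing, per-comparison
    differential expression by two-sample Student's t-test with a paired-comparison
    intersection rule, construction of a thresholded bipartite lncRNA-mRNA Pearson
    co-expression network with degree-based hub ranking and hub-centered subnetwork
    extraction, gene-set crosstalk tables and hypergeometric pathway enrichment with
    Benjamini-Hochberg correction, the single-cell RNA-seq quality-control filter
    cascade with per-step removal accounting, and integration of co-expression,
    protein-protein interaction and transcription-factor regulation layers around a
    focal gene. A synthetic-data generator plants differential expression, hub
    modules and low-quality cells so every stage of the pipeline is verifiable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment,
    SingleCellExperiment
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    igraph,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
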