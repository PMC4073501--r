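Package: cnvherd
Title: Copy Number Variation Analysis for Bovine Array CGH Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of array comparative genomic hybridization
    (aCGH) copy-number experiments in cattle-like multi-population panels:
    simulation of probe layouts, planted copy-number events and log2-ratio
    profiles; exact least-squares segmentation by dynamic programming; CNV
    calling by the mean-log2-ratio/minimum-probe rule; aggregation of
    per-sample CNVs into copy number variable regions (CNVRs) within and
    across groups with summary accounting; gene/QTL annotation by overlap
    fraction; hierarchical clustering and indicator-value permutation
    statistics on the sample-by-CNVR presence matrix; relative copy number
    and expression fold change from qPCR Ct tables by the delta-delta-Ct
    method; and association of CNVR genotypes with growth traits through a
    fixed-effects linear model with least-squares means.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
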