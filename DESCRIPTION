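Package: dysnet
Title: Co-Expression Module and Regulatory Network Dysregulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting immune network dysregulation between
    phenotype groups from stimulated expression data. Detects signed
    co-expression modules via topological overlap, summarizes them by module
    eigengenes, compares module connectivity networks between groups, infers
    group- and condition-specific transcription-factor regulatory networks by
    motif-prior message passing, computes per-TF per-module regulatory-shift
    statistics with silhouette-selected k-means TF communities, and tests the
    spatial proximity of TF binding locations within differentially
    methylated regions by a smoothed binding-profile silhouette permutation
    test. Includes a synthetic-data generator producing ground-truth-bearing
    count matrices, motifs, promoter and DMR sequences for benchmarking
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
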