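Package: permde
Title: Permutation-Null Differential Expression for Matched-Pair Embryo
    Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-condition, matched-pair bulk RNA-seq
    designs with very few replicates, modelled on transcriptome comparisons of
    embryos conceived with fresh versus frozen-thawed sperm.  Implements TPM
    and RPKM quantification with an expression floor, a genome-pooled
    permutation null for per-gene expression differences crossed with a
    fold-change filter, volcano construction, EASE-style gene-set
    over-representation with Benjamini-Hochberg control, confidence-thresholded
    interaction-network analysis with a permutation PPI-enrichment test, and
    intersection of candidate genes with ortholog-phenotype annotations.  A
    negative-binomial simulator with planted condition effects makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
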