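Package: convtrace
Title: Lineage-Traced Single-Nucleus Analysis of Glia-to-Neuron Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-nucleus RNA-seq studies of direct
    glia-to-neuron reprogramming with viral lineage barcodes. Provides a
    ground-truthed synthetic-data generator (negative-binomial counts for
    glial subpopulations and an emerging neuronal population, Poisson-MOI
    transgene copies, clone-structured barcode FASTQ reads), quality
    filtering and normalization, highly-variable-gene selection, graph-based
    Louvain clustering with marker annotation, rank-sum differential
    expression, binned-control gene-module scoring, a permutation test for
    differential cluster abundance with bootstrap confidence intervals,
    per-cell transgene calling with Fisher tests of conversion outcome, a
    motif-based barcode extraction and edit-distance error-correction
    pipeline, and a weighted compositional regression of clonal neuronal
    conversion rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
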