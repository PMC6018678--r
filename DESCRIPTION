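Package: crisprikit
Title: Design and Analysis of Pooled CRISPRi Screens in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for pooled CRISPR interference (CRISPRi) functional
    genomics in prokaryotes. Designs tiling or genome-scale sgRNA libraries
    from a genome and its annotation under a region-weighted off-target
    penalty metric, GC-content filtering, sequence-similarity gene
    clustering and position-aware guide selection; extracts and counts
    spacers from pooled-screen sequencing reads; estimates sgRNA and gene
    fitness from count tables with an empirical false-positive-rate null
    built from negative-control quasi genes, Storey-Tibshirani q-values and
    adaptive 5'-proximal subset selection; and benchmarks essentiality
    classifiers (CRISPRi score, transposon insertion index, genetic
    footprinting) by ROC analysis. Includes seed-deterministic simulators
    for genomes, screens, reads and transposon-insertion tables so the full
    pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
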