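Package: chromprot
Title: Quality Scoring, Differential Binding and Genomic Integration for
    Chromatin Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for ChIP-based chromatin proteomics
    experiments. Provides enrichment filtering against no-antibody
    controls, abundance ranking and bait quality checks, intensity-fraction
    specificity scoring of potential true and false positive protein
    classes, contamination accounting for affinity reagents, SILAC
    two-condition differential chromatin-binding tests, ratio-matrix
    clustering, genomic peak colocalization and proximity assignment,
    differential occupancy, and double-knockdown genetic-interaction
    classification. Includes a synthetic-data generator with planted
    ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
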