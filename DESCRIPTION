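Package: introcold
Title: Time-Course Cold-Stress Transcriptome Comparison for Introgression Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the cold-stress transcriptome of a chromosome-segment
    introgression line against its recurrent parent across a time course.
    Implements permutation-based SAM differential expression with a linear
    fold-change gate, phase-structured classification of cold-responsive gene
    sets (common, genotype-specific, continuous, constitutive), average-linkage
    correlation clustering of expression patterns, DRE/CRT promoter-motif
    regulon construction with driver co-expression, hypergeometric GO-term
    enrichment, co-localization of differential genes with introgressed
    segments and QTL intervals, the electrolyte-leakage injury statistic, and
    a synthetic-data generator with planted ground truth so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
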