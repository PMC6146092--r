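Package: kappaseq
Title: Immunoglobulin Kappa Repertoire Sequencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing immunoglobulin kappa light-chain (VkJk)
    repertoires sequenced from genomic DNA and 5' RACE cDNA libraries of mouse
    pro-B and pre-B cells. Covers the annotated Igk locus model, read trimming
    and paired-end merging, Vk/Jk assignment with identity and length cutoffs,
    UMI-based deduplication with reallocation between 3'-identical Vk gene
    pairs, repertoire frequency and ratio statistics, window-based
    quantification of chromatin and RNA coverage tracks, and random-forest
    classification/regression of rearrangement activity with variable
    importance and recursive feature elimination. A fully ground-truthed
    synthetic-data module generates gDNA/RNA FASTQ libraries and planted-effect
    coverage tracks so that every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    randomForest,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
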