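Package: meiotrans
Title: Transcription Landscapes and Recombination in Early Meiosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of early-meiotic transcription and its
    relationship to meiotic recombination in Drosophila-style genomes:
    windowed transcription landscapes (gene counts, kilobases transcribed,
    overall transcriptional activity), Wald-Wolfowitz runs tests for physical
    clustering of expressed genes, Monte-Carlo enrichment of double-strand
    breaks across transcription categories, parent-of-origin (maternal-like)
    expression classification, allele-specific read assignment against
    parental haplotypes, and a staged filter cascade for candidate novel
    transcripts. A synthetic-data generator produces every input the pipeline
    consumes, with planted effects whose recovery is tested.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
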