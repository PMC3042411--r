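Package: ighvdup
Title: Haplotype Phasing and Segmental Duplication Analysis for the
    Human IGHV Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing polymorphic segmental-duplication regions
    of the human immunoglobulin heavy chain variable (IGHV) locus.
    Simulates IGHV-like regions carrying tandem duplicate blocks and donor
    haplotype pairs, selects unique non-coding sequence tags and designs
    the multiplex PCR and single-base-extension oligo set for each tag,
    simulates and phases noisy presence/absence tag assays on panels of
    single sperm, discovers duplicate blocks by dot-matrix self-comparison,
    accounts for allelic versus paralogous divergence between gene-segment
    copies, and implements a mutational-clock model for pseudogenization
    and duplication timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
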