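#' The published 17-tag assay panel for the IGHV duplication region
#'
#' The reference set of unique non-coding DNA sequence tags covering the
#' polymorphic segmental-duplication region of the IGHV locus on chromosome
#' 14, with the four oligos of each tag (forward, reverse and nested PCR
#' primers, and the single-base-extension microarray probe). Tag names are
#' "VHS" plus the proximal kb offset; `from`/`to` are 1-based positions on
#' the GenBank AB019439 coordinate system the panel was designed on.
#'
#' @return a tibble `name`, `from`, `to`, `forward`, `reverse`, `nested`,
#'   `probe`, ordered by position.
#' @export
ighv_tag_panel <- function() {
  tribble_rows <- list(
    list("VHS429", 428971L, 429130L, "ATATATACAAGATTAGTCCCACAATA", "ATACCAGCTCTACTATATATGAAAGTC", "TATGCAAGCATTAGATACCCATA", "AAACCATGCTGTCGCAGGGTC"),
    list("VHS437", 437246L, 437398L, "CACAAAATGCAGATTCACACTC", "AGCCTGTTCTAGTCATGGAATCTC", "GAAAAGTCCTCAACTGTGGTCA", "CCAGGAACGCCTGAGATTCCT"),
    list("VHS444", 444731L, 444867L, "CACCCCTTCACAACTGGGGAT", "TGGTAGCGCTGTGAGGTGATA", "TGGGGCAGGACACAAATCCAA", "TACCTGACCACCATGCGTATT"),
    list("VHS449", 449260L, 449427L, "GAACAGACAACCTGTGAATGGT", "ATTTCTGTTGAACACTTGTATGTCT", "AAATGTGCAGTCTATTCATCAAAT", "TATCTCGTTTTTGCTCACTCT"),
    list("VHS454", 454027L, 454155L, "TATTACCAGGAGACCAAAATCTC", "AAAGGAAGGTTGCTGGTAAGG", "ATACAGACAAACAGGCGAAGG", "GATTGCCTTTCGCCACATAGA"),
    list("VHS458", 458073L, 458214L, "CGAAATATAATTCTTGCTCTTCTG", "CAGGAGAATTATGAACATTGAGAG", "AGCACATCCTAGCATCCCTGT", "CATCGGCGTGTTTACATCTAC"),
    list("VHS462", 462778L, 462952L, "CGTTAGCTCTGTGAAAGCAGC", "TGATTTGTTCCCTTAGTTTCTGG", "CAGGTTTACTGTTAAGGAGGTCA", "TGGCTACTCAGCGTGCAAATG"),
    list("VHS468", 468656L, 468843L, "TTAGCATCTCCTATTTGAGTAGATTT", "TCTAGATATTCAGGAGGCTAATACA", "TGTTCCACAGCTTAAAGTACAGTT", "TGAGTCCGGAGCTCAAAATTA"),
    list("VHS475", 475730L, 475892L, "TGTAGTTTCCTTTATTGTGGTGC", "AATTCTTCCCAACAGAAAAGTG", "TTACTGGTAATACTATCATGGTAGTC", "AGGTAGTCTGCCATACACCTT"),
    list("VHS479", 479662L, 479810L, "GAAGCAAATTGATTAGTGTGCAG", "CAGCTGAATCGCTTTTGGTC", "TCTGCTTTGCCTGCTATTCAT", "TGAGAAACACACGGGTCTTAT"),
    list("VHS485", 485677L, 485819L, "GCTGTCTCCTAAGTAAGTCACAGG", "AGGGATTCAGTGCAAATTGAG", "ACACACCAACATCACCAACAT", "TCTATAGTTCGTTCGAGGAAGT"),
    list("VHS493", 493051L, 493239L, "GAGTGAGCCTTAAGTAATCAACAG", "CCCATCCCCTCCTTCTTTCTC", "TGACAACTTATTCTAGGTAGCAAGA", "CTGGGTCTTGTCCATCGATAC"),
    list("VHS499", 499270L, 499449L, "CTGAAGCTGCTTAATCACCGT", "TGTGTATTGATTTGACAAAACACTA", "TCTGCTCTGATGGAATCAGGG", "ATCGGTTGACTCTATGTTAGG"),
    list("VHS504", 504031L, 504171L, "TGTGGGTTGTTCTCACCATAATA", "ACAACTGGATGCACCTCCATA", "CCACCAGACACCCTCCAATAC", "CACTCCGACACATTATAAGAGA"),
    list("VHS510", 509963L, 510127L, "GTCGTGTATCTCACTTTCCACTA", "TTTAGTGGGATTTTAGAGAGTACAA", "GATGGAGTCCTGATCCCTGCC", "TTTCTGTGACCGTGTGTCACT"),
    list("VHS514", 514084L, 514235L, "GAGTGTGGACTGATCCATTGC", "ATACCATGTGCTGCTGACACC", "ATAGAATCCTTGCTTGGGGTCT", "CTAAACTGGCCGTAGGAAAGC"),
    list("VHS518", 518664L, 518809L, "CAAACCTGTCAGGGCACTTAG", "TGACAGTAAACCAGCCTCTCAT", "TCCAGGAAGACTCAAGACCAC", "CCCCAAGTGGTCGTGAGTCCC")
  )
  map_dfr(tribble_rows, function(r) {
    tibble(
      name = r[[1]], from = r[[2]], to = r[[3]],
      forward = r[[4]], reverse = r[[5]], nested = r[[6]], probe = r[[7]]
    )
  })
}

#' Reference haplotype calls for the 17-tag panel across six sperm donors
#'
#' The per-haplotype tag genotypes (detected `+`, undetectable `ud`,
#' unresolved `-`) determined by single-sperm typing of six unrelated
#' donors — two phased haplotypes per donor, twelve haplotype columns in
#' all. Tags VHS458, VHS479 and VHS504 are undetectable in every
#' haplotype; six tags between VHS468 and VHS510 are polymorphic.
#'
#' @return a tibble `tag`, `donor`, `haplotype`, `status`, with tags in
#'   genomic order (also in attribute `tag_order`).
#' @export
ighv_haplotype_calls <- function() {
  donors <- c("#002", "#12", "AB005", "AB027", "AC09", "D18")
  cols <- paste(rep(donors, each = 2), rep(c("H1", "H2"), 6), sep = "/")
  status_rows <- list(
    VHS429 = rep("+", 12),
    VHS437 = rep("+", 12),
    VHS444 = rep("+", 12),
    VHS449 = rep("+", 12),
    VHS454 = rep("+", 12),
    VHS458 = rep("ud", 12),
    VHS462 = rep("+", 12),
    VHS468 = c("+", "+", "ud", "ud", "+", "+", "+", "ud", "+", "+", "+", "+"),
    VHS475 = c("+", "+", "ud", "ud", "+", "+", "+", "ud", "+", "+", "ud", "+"),
    VHS479 = rep("ud", 12),
    VHS485 = c("+", "+", "ud", "+", "+", "+", "+", "-", "+", "+", "+", "+"),
    VHS493 = c("+", "+", "ud", "+", "+", "+", "+", "-", "+", "+", "+", "+"),
    VHS499 = c("+", "+", "ud", "+", "+", "+", "+", "-", "+", "+", "+", "+"),
    VHS504 = rep("ud", 12),
    VHS510 = c("+", "+", "ud", "+", "+", "+", "+", "+", "+", "+", "+", "+"),
    VHS514 = rep("+", 12),
    VHS518 = rep("+", 12)
  )
  out <- map_dfr(names(status_rows), function(tg) {
    tibble(
      tag = tg,
      donor = rep(donors, each = 2),
      haplotype = rep(c("H1", "H2"), 6),
      status = status_rows[[tg]]
    )
  })
  attr(out, "tag_order") <- names(status_rows)
  attr(out, "columns") <- cols
  out
}

#' Reference divergence rows for closely related IGHV gene segments
#'
#' The published pairwise differences between the closest gene-segment
#' counterparts in and around the duplicated region: allelic pairs between
#' the two assembly haplotypes, and paralogous pairs within each assembly
#' (between Repeats I, II and the incomplete Repeat III). `denominator`
#' holds the printed length cell that the printed percent is computed from
#' (the second sequence's length for most rows; two boundary rows divide by
#' the first). `consistent` flags rows whose printed cells reproduce the
#' printed percent; the one row with irreconcilable length cells is kept
#' but flagged.
#'
#' @return a tibble `name_a`, `len_a`, `name_b`, `len_b`, `diff`,
#'   `percent`, `relation`, `group`, `denominator`, `consistent`.
#' @export
ighv_divergence_rows <- function() {
  r <- list(
    list("4-28.1P", 253L, "4-28.2P", 255L, 2L, 0.78, "allelic", "GRCh37/HuRef", 255L, TRUE),
    list("3-29P", 458L, "3-29.1P", 458L, 6L, 1.31, "allelic", "GRCh37/HuRef", 458L, TRUE),
    list("3-30", 454L, "3-30.1", 454L, 1L, 0.22, "allelic", "GRCh37/HuRef", 454L, TRUE),
    list("4-31", 438L, "4-28.1a", 438L, 19L, 4.34, "allelic", "GRCh37/HuRef", 438L, TRUE),
    list("4-31", 438L, "4-31.1", 438L, 8L, 1.83, "allelic", "GRCh37/HuRef", 438L, TRUE),
    list("3-33", 454L, "3-33.1", 202L, 3L, 1.49, "allelic", "GRCh37/HuRef", 202L, TRUE),
    list("4-28", 435L, "4-31", 438L, 29L, 6.62, "paralogous", "GRCh37", 438L, TRUE),
    list("4-28.1P", 253L, "4-31.1P", 255L, 12L, 4.71, "paralogous", "GRCh37", 255L, TRUE),
    list("3-29P", 458L, "3-32P", 458L, 13L, 2.84, "paralogous", "GRCh37", 458L, TRUE),
    list("3-30", 454L, "3-33", 454L, 4L, 0.88, "paralogous", "GRCh37", 454L, TRUE),
    list("4-30.1P", 274L, "4-33.1", 274L, 5L, 1.82, "paralogous", "GRCh37", 274L, TRUE),
    list("3-30.2P", 449L, "3-33.2P", 449L, 8L, 1.78, "paralogous", "GRCh37", 449L, TRUE),
    # boundary rows against the incomplete Repeat III copy (4-34) divide by
    # the first length in this assembly's block of the table
    list("4-28", 438L, "4-34", 433L, 41L, 9.36, "paralogous", "GRCh37", 438L, FALSE),
    list("4-31", 438L, "4-34", 433L, 43L, 9.82, "paralogous", "GRCh37", 438L, TRUE),
    list("4-28", 435L, "4-28.1a", 438L, 28L, 6.39, "paralogous", "HuRef", 438L, TRUE),
    list("4-28", 435L, "4-31.1", 438L, 15L, 3.42, "paralogous", "HuRef", 438L, TRUE),
    list("4-28.1a", 438L, "4-31.1", 438L, 17L, 3.88, "paralogous", "HuRef", 438L, TRUE),
    list("3-30.1", 454L, "3-33.1", 202L, 3L, 1.49, "paralogous", "HuRef", 202L, TRUE),
    list("4-28.1a", 438L, "4-34", 433L, 43L, 9.93, "paralogous", "HuRef", 433L, TRUE),
    list("4-31.1", 438L, "4-34", 433L, 41L, 9.47, "paralogous", "HuRef", 433L, TRUE)
  )
  map_dfr(r, function(x) {
    tibble(
      name_a = x[[1]], len_a = x[[2]], name_b = x[[3]], len_b = x[[4]],
      diff = x[[5]], percent = x[[6]], relation = x[[7]], group = x[[8]],
      denominator = x[[9]], consistent = x[[10]]
    )
  })
}
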