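#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment (via Biostrings) under a simple
#' scoring scheme; returns the gapped sequences together with the column
#' bookkeeping the divergence accounting needs: substitution columns, gap
#' (indel) columns and indel events (maximal gap runs in either sequence).
#'
#' @param a,b nucleotide sequences.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (penalties as negative numbers). A gap of length k costs
#'   `|gap_open| + k * |gap_extend|`.
#' @return a `pairwise_alignment` object: list with `aligned_a`,
#'   `aligned_b`, `n_columns`, `n_substitutions`, `n_indel_events`,
#'   `n_indel_columns`, `score`.
#' @export
#' @examples
#' al <- global_align("ACGT", "ACTT")
#' al$n_substitutions
global_align <- function(a, b,
                         scoring = list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)) {
  a <- as_seq(a)
  b <- as_seq(b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE
  )
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend)
  )
  ga <- as.character(Biostrings::alignedPattern(al))
  gb <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(ga, "", fixed = TRUE)[[1]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  n_events <- function(g) sum(diff(c(FALSE, g)) == 1)
  structure(
    list(
      aligned_a = ga, aligned_b = gb,
      n_columns = base::length(ca),
      n_substitutions = sum(!gap_a & !gap_b & ca != cb),
      n_indel_events = n_events(gap_a) + n_events(gap_b),
      n_indel_columns = sum(gap_a | gap_b),
      score = Biostrings::score(al)
    ),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "<pairwise_alignment> %d columns, %d substitutions, %d indel events (%d columns), score %.1f\n",
    x$n_columns, x$n_substitutions, x$n_indel_events, x$n_indel_columns, x$score
  ))
  invisible(x)
}

#' @export
glance.pairwise_alignment <- function(x, ...) {
  tibble(
    n_columns = x$n_columns, n_substitutions = x$n_substitutions,
    n_indel_events = x$n_indel_events, n_indel_columns = x$n_indel_columns,
    score = x$score
  )
}

#' Count differences in an alignment under a named convention
#'
#' The published difference counts do not state how indels enter; the
#' convention is therefore explicit: `subs_only`, `subs_plus_indel_events`
#' (each maximal gap run counts once; the default, the most conservative
#' reading that still counts unequal-length pairs) or
#' `subs_plus_indel_columns` (each gap column counts).
#'
#' @param al a `pairwise_alignment`.
#' @param convention counting rule.
#' @return integer difference count.
#' @export
count_differences <- function(al, convention = c(
                                "subs_plus_indel_events", "subs_only", "subs_plus_indel_columns"
                              )) {
  convention <- match.arg(convention)
  switch(convention,
    subs_only = al$n_substitutions,
    subs_plus_indel_events = al$n_substitutions + al$n_indel_events,
    subs_plus_indel_columns = al$n_substitutions + al$n_indel_columns
  )
}

#' Percent difference at printed precision
#'
#' `100 * diff / denominator`, rounded half-up to 2 decimals — the precision
#' at which gene-segment divergence tables print.
#'
#' @param diff difference count, bp.
#' @param denominator denominator length, bp.
#' @return percent, 2 decimals.
#' @export
#' @examples
#' percent_difference(29, 438) # 6.62
#' percent_difference(39, 2245) # pooled allelic 1.74
percent_difference <- function(diff, denominator) {
  stopifnot(denominator > 0)
  round_half_up(100 * diff / denominator, 2)
}

#' Translate a percent difference into bases per 1,200 bp
#'
#' The genomic average of one substitution per 1,200 bp is 0.08%; this
#' helper converts a percent difference onto that scale (1 decimal,
#' half-up).
#'
#' @param percent percent difference.
#' @return bases per 1,200 bp, 1 decimal.
#' @export
#' @examples
#' per_1200(4.34) # 52.1
#' per_1200(0.22) # 2.6
per_1200 <- function(percent) {
  round_half_up(percent / 100 * 1200, 1)
}

#' Open-reading-frame status of a gene segment's exons
#'
#' Concatenates the exons, reads codons in the given frame and reports
#' whether any stop codon appears before the final codon. The final codon
#' may be a stop (a natural terminator does not break the ORF); a trailing
#' partial codon is ignored.
#'
#' @param exons character vector of exon sequences, 5' to 3'.
#' @param frame 0-based reading-frame offset.
#' @return a tibble `in_orf` (logical), `first_stop_position` (0-based codon
#'   index, `NA` when in frame).
#' @export
orf_status <- function(exons, frame = 0) {
  cds <- substr(paste(exons, collapse = ""), frame + 1L, .Machine$integer.max)
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) {
    return(tibble(in_orf = TRUE, first_stop_position = NA_integer_))
  }
  codons <- substring(cds, 3L * (seq_len(n_codon) - 1L) + 1L, 3L * seq_len(n_codon))
  aa <- Biostrings::GENETIC_CODE[codons]
  internal <- unname(which(unname(aa) == "*" & seq_len(n_codon) < n_codon))
  tibble(
    in_orf = base::length(internal) == 0,
    first_stop_position = if (base::length(internal)) internal[1] - 1L else NA_integer_
  )
}

#' Build a divergence table for allelic and paralogous sequence pairs
#'
#' One record per pair: lengths, aligned difference count (under the chosen
#' convention), percent difference (under the chosen denominator) and the
#' stated relation. Group summaries pool differences and denominators per
#' relation, reproducing the "total"-row arithmetic of published divergence
#' tables.
#'
#' @param pairs a tibble with columns `name_a`, `seq_a`, `name_b`, `seq_b`,
#'   `relation` (`allelic` or `paralogous`).
#' @param convention difference-counting rule, see [count_differences()].
#' @param denominator which length divides the difference count: `len_b`
#'   (the second sequence; the default), `len_a`, `longer`, `shorter` or
#'   `alignment_columns`.
#' @param scoring alignment scoring passed to [global_align()].
#' @return a `divergence_table` object: list of `records` and `groups`
#'   tibbles; `tidy()` returns the records, `glance()` the group summaries.
#' @export
build_divergence_table <- function(pairs,
                                   convention = "subs_plus_indel_events",
                                   denominator = c("len_b", "len_a", "longer", "shorter", "alignment_columns"),
                                   scoring = list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)) {
  denominator <- match.arg(denominator)
  records <- map_dfr(seq_len(nrow(pairs)), function(k) {
    al <- global_align(pairs$seq_a[k], pairs$seq_b[k], scoring)
    len_a <- nchar(pairs$seq_a[k])
    len_b <- nchar(pairs$seq_b[k])
    den <- switch(denominator,
      len_a = len_a, len_b = len_b,
      longer = max(len_a, len_b), shorter = min(len_a, len_b),
      alignment_columns = al$n_columns
    )
    d <- count_differences(al, convention)
    tibble(
      name_a = pairs$name_a[k], len_a = len_a,
      name_b = pairs$name_b[k], len_b = len_b,
      diff = d, denominator = den,
      percent = percent_difference(d, den),
      relation = pairs$relation[k]
    )
  })
  records <- arrange(records, .data$relation, .data$name_a, .data$name_b)
  groups <- records |>
    group_by(.data$relation) |>
    summarise(
      n_pairs = dplyr::n(),
      total_diff = sum(.data$diff),
      total_denominator = sum(.data$denominator),
      pooled_percent = percent_difference(sum(.data$diff), sum(.data$denominator)),
      .groups = "drop"
    )
  structure(
    list(records = records, groups = groups, convention = convention, denominator = denominator),
    class = "divergence_table"
  )
}

#' @export
print.divergence_table <- function(x, ...) {
  cat(sprintf(
    "<divergence_table> %d pairs (%s differences / %s denominator)\n",
    nrow(x$records), x$convention, x$denominator
  ))
  print(x$records)
  print(x$groups)
  invisible(x)
}

#' @describeIn build_divergence_table tidy method: one row per sequence pair.
#' @param x a `divergence_table`.
#' @param ... unused.
#' @export
tidy.divergence_table <- function(x, ...) x$records

#' @describeIn build_divergence_table glance method: pooled per-relation summaries.
#' @export
glance.divergence_table <- function(x, ...) x$groups
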