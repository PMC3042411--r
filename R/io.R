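#' Write regions (or plain sequences) to FASTA
#'
#' @param regions a single [annotated_region()], a list of them, or a named
#'   character vector of sequences.
#' @param path output file; lines wrapped at 60 bases.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(regions, path) {
  if (inherits(regions, "annotated_region")) regions <- list(regions)
  seqs <- if (is.character(regions)) {
    regions
  } else {
    stats::setNames(
      map_chr(regions, as_seq),
      map_chr(regions, function(r) if (inherits(r, "annotated_region")) r$name else "seq")
    )
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read FASTA into a named character vector of sequences
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta_seqs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write a region's features as BED
#'
#' BED convention: 0-based half-open intervals, chrom = region name, the
#' feature name in the name column, score 0, strand column kept.
#'
#' @param region an [annotated_region()].
#' @param path output file.
#' @param kind optional feature kind filter.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(region, path, kind = NULL) {
  f <- region_features(region, kind)
  gr <- GenomicRanges::GRanges(
    seqnames = region$name,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand,
    name = f$name,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a feature-style tibble
#'
#' @param path BED file.
#' @return a tibble `chrom`, `start` (0-based), `end`, `name`, `strand`.
#' @export
read_features_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = gr$name,
    strand = as.character(BiocGenerics::strand(gr))
  )
}

#' Write a sperm genotype matrix as TSV (rows sperm, columns tags, 0/1)
#'
#' @param gm a `sperm_genotypes` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  tags <- attr(gm, "tags") %||% unique(gm$tag)
  wide <- as_tibble(gm)[, c("sperm_id", "tag", "call")] |>
    mutate(call = as.integer(.data$call == "detected")) |>
    pivot_wider(names_from = "tag", values_from = "call")
  readr::write_tsv(wide[, c("sperm_id", tags)], path)
  invisible(path)
}

#' Read a sperm genotype TSV back into a long `sperm_genotypes` tibble
#'
#' @param path TSV written by [write_genotype_tsv()].
#' @param donor donor label to attach.
#' @return a `sperm_genotypes` tibble.
#' @export
read_genotype_tsv <- function(path, donor = "donor") {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  tags <- setdiff(names(wide), "sperm_id")
  out <- pivot_longer(wide, -"sperm_id", names_to = "tag", values_to = "x") |>
    mutate(call = ifelse(.data$x == 1L, "detected", "undetected")) |>
    dplyr::select("sperm_id", "tag", "call")
  structure(
    out,
    class = c("sperm_genotypes", class(out)),
    donor = donor, tags = tags
  )
}

#' Write a haplotype call table in the tags-by-haplotypes layout
#'
#' Rows are tags in genomic order, one column per donor/haplotype, symbols
#' `+`, `ud`, `-`.
#'
#' @param calls a tibble `tag`, `donor`, `haplotype`, `status`.
#' @param path output file.
#' @param tag_order optional tag order (defaults to appearance order).
#' @return `path`, invisibly.
#' @export
write_haplotype_table_tsv <- function(calls, path, tag_order = NULL) {
  tag_order <- tag_order %||% attr(calls, "tag_order") %||% unique(calls$tag)
  wide <- calls |>
    mutate(column = paste(.data$donor, .data$haplotype, sep = "/")) |>
    dplyr::select("tag", "column", "status") |>
    pivot_wider(names_from = "column", values_from = "status")
  readr::write_tsv(wide[match(tag_order, wide$tag), ], path)
  invisible(path)
}

#' Read a haplotype call table written by [write_haplotype_table_tsv()]
#'
#' @param path TSV file.
#' @return a long tibble `tag`, `donor`, `haplotype`, `status` with the
#'   `tag_order` attribute set.
#' @export
read_haplotype_table_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  out <- pivot_longer(wide, -"tag", names_to = "column", values_to = "status") |>
    tidyr::separate_wider_delim("column", "/", names = c("donor", "haplotype")) |>
    dplyr::select("tag", "donor", "haplotype", "status")
  attr(out, "tag_order") <- wide$tag
  out
}
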