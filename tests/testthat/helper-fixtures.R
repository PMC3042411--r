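# Shared fixture builders; everything is generated in code at test time.

fixed_templates <- function(n = 2, len = 450, seed = 100) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      gene_template(
        paste0("g", i), random_seq(len),
        exons = rbind(c(0, 60), c(len - 300, len)),
        functional = TRUE
      )
    })
  })
}

# A featureless region with one planted 2-complete + 1-partial duplication.
# Returns the region plus the planted truth boundaries.
planted_dup_region <- function(unit = 500, partial = 120, div = 0.0125,
                               flank5 = 400, flank3 = 300, seed = 1) {
  withr::with_seed(seed, {
    anc <- annotated_region("dup_fixture", random_seq(flank5 + unit + flank3))
    region <- plant_duplication(
      anc, c(flank5, flank5 + unit),
      duplication_spec(
        n_complete = 2, partial_length = partial,
        per_copy_divergence = div, seed = NULL
      )
    )
    list(
      region = region,
      truth_starts = c(flank5, flank5 + unit, flank5 + 2 * unit),
      truth_end = flank5 + 2 * unit + partial,
      unit = unit
    )
  })
}

# A 17-tag truth pattern pair with a deletion-style undetectable run on H2,
# two tags undetectable in both haplotypes, shaped like the phased panels
# the assay produces.
truth_pattern_pair <- function(n_tags = 17) {
  tags <- sprintf("T%02d", seq_len(n_tags))
  h1 <- rep(TRUE, n_tags)
  h2 <- rep(TRUE, n_tags)
  h1[c(6, 14)] <- FALSE # undetectable in H1 only
  h2[8:12] <- FALSE # consecutive undetectable run on H2
  h1[4] <- FALSE
  h2[4] <- FALSE # undetectable in every haplotype
  dplyr::bind_rows(
    tibble::tibble(haplotype = "H1", tag = tags, detectable = h1),
    tibble::tibble(haplotype = "H2", tag = tags, detectable = h2)
  )
}

status_sets <- function(phasing) {
  wide <- tidyr::pivot_wider(
    phasing$haplotypes[, c("haplotype", "tag", "status")],
    names_from = "haplotype", values_from = "status"
  )
  sort(c(paste(wide$H1, collapse = ""), paste(wide$H2, collapse = "")))
}

truth_status_sets <- function(truth) {
  wide <- tidyr::pivot_wider(truth, names_from = "haplotype", values_from = "detectable")
  s <- function(x) paste(ifelse(x, "+", "ud"), collapse = "")
  sort(c(s(wide$H1), s(wide$H2)))
}
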