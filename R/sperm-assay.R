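#' Noise model for the single-sperm tag assay
#'
#' Detection is binary: a truly detectable tag reads undetected with
#' probability `dropout` (allele dropout, failed amplification or weak
#' signal), and a truly absent tag reads detected with probability
#' `false_positive` (cross-hybridisation, contamination).
#'
#' @param dropout probability in `[0, 1)`.
#' @param false_positive probability in `[0, 1)`.
#' @param seed optional integer seed for the simulation.
#' @return a `noise_model` list.
#' @export
noise_model <- function(dropout = 0.05, false_positive = 0.01, seed = NULL) {
  if (dropout < 0 || dropout >= 1 || false_positive < 0 || false_positive >= 1) {
    abort("noise probabilities must be in [0, 1)", class = "ighv_parameter_error")
  }
  structure(
    list(dropout = dropout, false_positive = false_positive, seed = seed),
    class = "noise_model"
  )
}

#' Mismatch tolerances for tag detectability
#'
#' A tag is scored detectable on a haplotype when all four oligos still find
#' a workable site: primers tolerate up to `max_mismatch_primer`
#' substitutions overall but none (by default) within the 3'-terminal
#' window that the polymerase must extend from; the probe tolerates up to
#' `max_mismatch_probe` substitutions; and the single-base-extension
#' template base adjacent to the probe 3' end must equal the designed A/G
#' base, since a polymorphic extension base alone abolishes the signal.
#'
#' @param max_mismatch_primer substitutions tolerated across a primer site.
#' @param max_mismatch_probe substitutions tolerated across the probe site.
#' @param three_prime_window primer 3'-terminal window length, nt.
#' @param max_mismatch_three_prime substitutions tolerated in that window.
#' @return a `detection_rules` list.
#' @export
detection_rules <- function(max_mismatch_primer = 2, max_mismatch_probe = 1,
                            three_prime_window = 5, max_mismatch_three_prime = 0) {
  structure(
    list(
      max_mismatch_primer = as.integer(max_mismatch_primer),
      max_mismatch_probe = as.integer(max_mismatch_probe),
      three_prime_window = as.integer(three_prime_window),
      max_mismatch_three_prime = as.integer(max_mismatch_three_prime)
    ),
    class = "detection_rules"
  )
}

#' Does an oligo retain a workable site in a subject sequence?
#'
#' `three_prime = "right"` checks the final bases of the footprint (forward
#' oriented oligos), `"left"` the leading bases (the reverse primer's 3' end
#' maps to the left edge of its top-strand footprint).
#' @noRd
oligo_site_ok <- function(pattern, subject, max_mm, rules,
                          three_prime = c("right", "left", "none")) {
  three_prime <- match.arg(three_prime)
  hits <- Biostrings::matchPattern(pattern, subject,
    max.mismatch = max_mm, with.indels = FALSE
  )
  if (base::length(hits) == 0) {
    return(FALSE)
  }
  if (three_prime == "none") {
    return(TRUE)
  }
  w <- rules$three_prime_window
  pat_int <- utf8ToInt(pattern)
  for (site in as.character(hits)) {
    mism <- utf8ToInt(site) != pat_int
    window_mm <- if (three_prime == "right") sum(tail(mism, w)) else sum(head(mism, w))
    if (window_mm <= rules$max_mismatch_three_prime) {
      return(TRUE)
    }
  }
  FALSE
}

#' Score one tag's detectability on a haplotype sequence
#'
#' Undetectable when any primer or the probe has no site within tolerance
#' anywhere in the haplotype, when primer mismatches concentrate in the
#' 3'-terminal window, or when the extension-template base next to the
#' probe footprint no longer matches the designed A/G base.
#'
#' @param oligos a one-row oligo-set tibble (see [design_oligos()]).
#' @param haplotype_seq haplotype sequence (string or [annotated_region()]).
#' @param rules a [detection_rules()] list.
#' @return `"detectable"` or `"undetectable"`.
#' @export
tag_detectability <- function(oligos, haplotype_seq, rules = detection_rules()) {
  seq <- as_seq(haplotype_seq)
  subject <- if (inherits(haplotype_seq, "XString")) haplotype_seq else Biostrings::DNAString(seq)

  ok <- oligo_site_ok(oligos$forward, subject, rules$max_mismatch_primer, rules, "right") &&
    oligo_site_ok(oligos$nested, subject, rules$max_mismatch_primer, rules, "right") &&
    oligo_site_ok(revcomp(oligos$reverse), subject, rules$max_mismatch_primer, rules, "left")
  if (!ok) {
    return("undetectable")
  }

  footprint <- revcomp(oligos$probe)
  hits <- Biostrings::matchPattern(footprint, subject,
    max.mismatch = rules$max_mismatch_probe, with.indels = FALSE
  )
  if (base::length(hits) == 0) {
    return("undetectable")
  }
  starts <- BiocGenerics::start(hits)
  seq_chr <- as.character(subject)
  for (st in starts) {
    if (st > 1 && substr(seq_chr, st - 1L, st - 1L) == oligos$extension_base) {
      return("detectable")
    }
  }
  "undetectable"
}

#' Detectability of a whole tag panel on one haplotype
#'
#' @param oligo_panel tibble from [design_tag_panel()].
#' @param haplotype_seq haplotype sequence or [annotated_region()].
#' @param rules a [detection_rules()] list.
#' @return a tibble `tag`, `detectable` (logical), in panel order.
#' @export
panel_detectability <- function(oligo_panel, haplotype_seq, rules = detection_rules()) {
  subject <- Biostrings::DNAString(as_seq(haplotype_seq))
  tibble(
    tag = oligo_panel$tag,
    detectable = map_lgl(
      seq_len(nrow(oligo_panel)),
      function(i) tag_detectability(oligo_panel[i, ], subject, rules) == "detectable"
    )
  )
}

#' Simulate a noisy single-sperm tag-typing panel
#'
#' Each sperm carries H1 or H2 with probability 1/2; its true call for each
#' tag is that haplotype's detectability; dropout and false-positive noise
#' are applied independently per entry. The hidden truth (per-haplotype
#' detectability and per-sperm assignments) is attached as attributes for
#' evaluation only — the phasing functions never look at it.
#'
#' @param hap_pair list of two [annotated_region()] haplotypes (H1, H2).
#' @param oligo_panel tibble from [design_tag_panel()].
#' @param n_sperm number of sperm; `NULL` draws uniformly from 49-60, the
#'   panel sizes used in the sperm-typing study design this emulates.
#' @param noise a [noise_model()].
#' @param rules a [detection_rules()] list.
#' @param truth optional precomputed truth tibble (`haplotype`, `tag`,
#'   `detectable`) to skip the sequence scan.
#' @param donor donor label.
#' @return a `sperm_genotypes` tibble (`sperm_id`, `tag`, `call` with values
#'   `detected`/`undetected`) with attributes `donor`, `tags`, `truth`,
#'   `truth_assignment`.
#' @export
simulate_sperm_panel <- function(hap_pair, oligo_panel, n_sperm = NULL,
                                 noise = noise_model(), rules = detection_rules(),
                                 truth = NULL, donor = "donor") {
  if (is.null(truth)) {
    truth <- bind_rows(
      mutate(panel_detectability(oligo_panel, hap_pair[[1]], rules), haplotype = "H1"),
      mutate(panel_detectability(oligo_panel, hap_pair[[2]], rules), haplotype = "H2")
    )
  }
  tags <- unique(truth$tag)
  truth_wide <- pivot_wider(truth, names_from = "tag", values_from = "detectable")
  tmat <- as.matrix(truth_wide[, tags])
  rownames(tmat) <- truth_wide$haplotype

  with_seed_(noise$seed, {
    if (is.null(n_sperm)) n_sperm <- sample(49:60, 1)
    assignment <- sample(c("H1", "H2"), n_sperm, replace = TRUE)
    true_calls <- tmat[assignment, , drop = FALSE]
    flip_down <- matrix(
      stats::runif(n_sperm * base::length(tags)) < noise$dropout,
      nrow = n_sperm
    )
    flip_up <- matrix(
      stats::runif(n_sperm * base::length(tags)) < noise$false_positive,
      nrow = n_sperm
    )
    observed <- (true_calls & !flip_down) | (!true_calls & flip_up)
    sperm_ids <- sprintf("S%02d", seq_len(n_sperm))
    out <- tibble(
      sperm_id = rep(sperm_ids, each = base::length(tags)),
      tag = rep(tags, times = n_sperm),
      call = ifelse(as.vector(t(observed)), "detected", "undetected")
    )
    structure(
      out,
      class = c("sperm_genotypes", class(out)),
      donor = donor, tags = tags, truth = truth,
      truth_assignment = tibble(sperm_id = sperm_ids, haplotype = assignment),
      noise = noise[c("dropout", "false_positive")]
    )
  })
}
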