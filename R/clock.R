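#' Parameters of the pseudogenization mutational clock
#'
#' Defaults are the values the clock model is calibrated on: a human
#' genome-wide mutation rate of 1.1e-8 substitutions per base per haploid
#' genome per generation, a 25-year generation, ~355 bp of exon per IGHV
#' gene segment (leader plus V exon), a fraction 18/61 of sense codons one
#' substitution away from a stop, and a structural-inactivation rate twice
#' the point-mutation rate (among surveyed IGHV pseudogenes, truncations
#' and other structural changes outnumber point inactivations about 2:1).
#'
#' @param mu substitution rate per base per haploid genome per generation.
#' @param generation_years years per human generation.
#' @param exon_length total exon length per gene segment, bp.
#' @param f_stop fraction of sense codons reachable-to-stop by one
#'   substitution, treated as the per-mutation probability of creating a
#'   stop (the model's deliberate simplification; see
#'   [stop_mutation_fraction()] for the stricter per-mutation alternative).
#' @param structural_multiplier ratio of structural-inactivation to
#'   point-inactivation rate.
#' @return a `clock_params` list.
#' @export
clock_params <- function(mu = 1.1e-8, generation_years = 25, exon_length = 355,
                         f_stop = 18 / 61, structural_multiplier = 2) {
  stopifnot(
    mu > 0, generation_years > 0, exon_length > 0,
    f_stop > 0, f_stop < 1, structural_multiplier >= 0
  )
  structure(
    list(
      mu = mu, generation_years = generation_years, exon_length = exon_length,
      f_stop = f_stop, structural_multiplier = structural_multiplier
    ),
    class = "clock_params"
  )
}

#' Sense codons one substitution away from a stop codon
#'
#' Exhaustive enumeration: every sense codon of the code is mutated at each
#' of its three positions to each of the three alternative bases (nine
#' neighbours), and codons with at least one stop neighbour are collected.
#' Under the standard genetic code 18 of the 61 sense codons qualify.
#'
#' @param code a named codon-to-amino-acid table (stops coded `"*"`);
#'   defaults to the standard genetic code.
#' @return a tibble `codon`, `amino_acid`, `n_stop_neighbors` with one row
#'   per qualifying sense codon; the count is `nrow()` of the result.
#' @export
#' @examples
#' nrow(single_hit_stop_codons()) # 18
single_hit_stop_codons <- function(code = Biostrings::GENETIC_CODE) {
  stops <- names(code)[code == "*"]
  sense <- names(code)[code != "*"]
  rows <- map_dfr(sense, function(cod) {
    hits <- 0L
    for (pos in 1:3) {
      for (base in setdiff(DNA_BASES, substr(cod, pos, pos))) {
        neighbor <- cod
        substr(neighbor, pos, pos) <- base
        if (neighbor %in% stops) hits <- hits + 1L
      }
    }
    if (hits > 0L) {
      tibble(codon = cod, amino_acid = unname(code[cod]), n_stop_neighbors = hits)
    } else {
      NULL
    }
  })
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(codon = character(), amino_acid = character(), n_stop_neighbors = integer()))
  }
  arrange(rows, .data$codon)
}

#' Stop-creating fraction of the genetic code
#'
#' `codon_fraction` (default) is the share of sense codons with at least one
#' stop neighbour — the simplification the clock's printed calibration
#' rests on. `per_mutation` is the stricter share of all `61 * 9` single-base
#' mutations that land on a stop; it gives a smaller fraction and hence
#' longer point-inactivation times, and is exposed as an alternative mode.
#'
#' @param code codon table as in [single_hit_stop_codons()].
#' @param mode `"codon_fraction"` or `"per_mutation"`.
#' @return a fraction in (0, 1).
#' @export
stop_mutation_fraction <- function(code = Biostrings::GENETIC_CODE,
                                   mode = c("codon_fraction", "per_mutation")) {
  mode <- match.arg(mode)
  tab <- single_hit_stop_codons(code)
  n_sense <- sum(code != "*")
  switch(mode,
    codon_fraction = nrow(tab) / n_sense,
    per_mutation = sum(tab$n_stop_neighbors) / (n_sense * 9)
  )
}

#' Expected time to pseudogenize a gene segment by point mutation
#'
#' The waiting time for a stop-creating substitution in the exons:
#' `generation_years / (mu * exon_length * f_stop)` years. With the default
#' calibration this is about 21.7 million years.
#'
#' @param p a [clock_params()] list.
#' @return years (unrounded).
#' @export
time_to_pseudogene_point <- function(p = clock_params()) {
  p$generation_years / (p$mu * p$exon_length * p$f_stop)
}

#' Expected time to inactivate a gene segment by any alteration
#'
#' Structural changes (mostly truncations by unequal crossover) inactivate
#' at `structural_multiplier` times the point rate, so the combined waiting
#' time is the point time divided by `1 + structural_multiplier` — about
#' 7.2 million years under the defaults.
#'
#' @param p a [clock_params()] list.
#' @return years (unrounded).
#' @export
time_to_pseudogene_all <- function(p = clock_params()) {
  time_to_pseudogene_point(p) / (1 + p$structural_multiplier)
}

#' Time needed to accumulate a given divergence
#'
#' Single-lineage accumulation, `d * generation_years / mu` years: the
#' convention under which a 4.36% difference between duplicate blocks
#' corresponds to about 99 million years. (A two-lineage convention,
#' `d * G / (2 mu)`, would halve this; the single-lineage form is the one
#' this model is calibrated to.)
#'
#' @param d divergence as a fraction (e.g. `0.0436`).
#' @param p a [clock_params()] list.
#' @return years (unrounded).
#' @export
divergence_time <- function(d, p = clock_params()) {
  stopifnot(d >= 0)
  d * p$generation_years / p$mu
}

#' Assemble the mutational-clock report
#'
#' @param d observed divergence fraction between duplicate copies.
#' @param p a [clock_params()] list.
#' @return a `clock_report` object: list with `t_point_years`,
#'   `t_all_years`, `t_divergence_years`, `ratio`
#'   (`t_divergence / t_all`) and the parameters used. Values are kept
#'   unrounded; printing formats millions of years at one decimal.
#' @export
#' @examples
#' clock_report(0.0436)
clock_report <- function(d, p = clock_params()) {
  t_point <- time_to_pseudogene_point(p)
  t_all <- time_to_pseudogene_all(p)
  t_div <- divergence_time(d, p)
  structure(
    list(
      d = d,
      t_point_years = t_point, t_all_years = t_all,
      t_divergence_years = t_div, ratio = t_div / t_all,
      params = p
    ),
    class = "clock_report"
  )
}

#' Format years as millions of years at one decimal
#' @param years numeric years.
#' @return character, e.g. `"21.7"`.
#' @export
format_my <- function(years) {
  sprintf("%.1f", round_half_up(years / 1e6, 1))
}

#' @export
print.clock_report <- function(x, ...) {
  cat("<clock_report>\n")
  cat(sprintf(
    "  point-mutation pseudogenization time: %s million years\n",
    format_my(x$t_point_years)
  ))
  cat(sprintf(
    "  all-alterations inactivation time:    %s million years\n",
    format_my(x$t_all_years)
  ))
  cat(sprintf(
    "  time to %.2f%% divergence:             %s million years\n",
    100 * x$d, format_my(x$t_divergence_years)
  ))
  cat(sprintf("  divergence / inactivation ratio:      %.1f\n", x$ratio))
  invisible(x)
}

#' @describeIn clock_report tidy method: one row per clock quantity.
#' @param x a `clock_report`.
#' @param ... unused.
#' @export
tidy.clock_report <- function(x, ...) {
  tibble(
    quantity = c("t_point", "t_all", "t_divergence"),
    years = c(x$t_point_years, x$t_all_years, x$t_divergence_years),
    millions_of_years = round_half_up(years / 1e6, 1)
  )
}

#' @describeIn clock_report glance method: the full report as one row.
#' @export
glance.clock_report <- function(x, ...) {
  tibble(
    d = x$d,
    t_point_years = x$t_point_years,
    t_all_years = x$t_all_years,
    t_divergence_years = x$t_divergence_years,
    ratio = x$ratio
  )
}
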