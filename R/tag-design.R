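#' Select unique non-coding sequence tags across a region
#'
#' Greedy left-to-right selection: past each spacing boundary, the first
#' window that (a) overlaps no gene segment and (b) occurs exactly once in
#' the region (exact forward-strand match) becomes a tag. Consecutive tag
#' starts are kept at least half a spacing apart; a boundary whose interval
#' offers no feasible window is skipped and recorded as a warning row.
#' Tag names follow the "VHS" + kb-offset convention.
#'
#' @param region an [annotated_region()].
#' @param spacing target spacing between tags, bp (must exceed `max_len`).
#' @param max_len maximum tag length, bp.
#' @param tag_length tag window length actually used, bp (`<= max_len`).
#' @return a tibble with columns `name`, `start`, `end`, `length`, ordered
#'   by position, with a `skipped` attribute listing infeasible boundaries.
#' @export
select_tags <- function(region, spacing = 5000, max_len = 225, tag_length = 160) {
  stopifnot(inherits(region, "annotated_region"))
  if (spacing <= max_len) {
    abort("spacing must exceed max_len", class = "ighv_parameter_error")
  }
  if (tag_length > max_len) {
    abort("tag_length must not exceed max_len", class = "ighv_parameter_error")
  }
  subject <- Biostrings::DNAString(region$seq)
  len <- region_length(region)
  genes <- region_features(region, "gene_segment")
  genes <- genes[order(genes$start), ]

  boundaries <- seq(0L, len - tag_length, by = spacing)
  rows <- list()
  skipped <- integer(0)
  prev_start <- -Inf
  for (b in boundaries) {
    p <- max(b, ceiling(prev_start + spacing / 2))
    limit <- min(b + spacing - 1L, len - tag_length)
    found <- FALSE
    while (p <= limit) {
      hit <- which(genes$start < p + tag_length & genes$end > p)
      if (base::length(hit)) {
        p <- max(genes$end[hit]) # jump past the blocking gene segment
        next
      }
      w <- seq_window(region$seq, p, p + tag_length)
      if (Biostrings::countPattern(w, subject, max.mismatch = 0) == 1L) {
        rows[[base::length(rows) + 1L]] <- tibble(
          name = paste0("VHS", round_half_up(p / 1000)),
          start = as.integer(p), end = as.integer(p + tag_length),
          length = as.integer(tag_length)
        )
        prev_start <- p
        found <- TRUE
        break
      }
      p <- p + 1L
    }
    if (!found) {
      warn(sprintf("no unique non-coding tag window after boundary %d", b))
      skipped <- c(skipped, b)
    }
  }
  out <- if (base::length(rows)) bind_rows(rows) else {
    tibble(name = character(), start = integer(), end = integer(), length = integer())
  }
  # kb-offset names can collide when spacing drops below 1 kb
  out$name <- make.unique(out$name, sep = "_")
  attr(out, "skipped") <- skipped
  out
}

#' Count occurrences of a subsequence within a region
#'
#' Forward-strand sliding-window count within `max_mismatch` substitutions
#' (no indels); a window taken verbatim from the region counts itself.
#'
#' @param subseq query nucleotide sequence.
#' @param region an [annotated_region()] or a plain sequence string.
#' @param max_mismatch allowed substitutions per window.
#' @return integer occurrence count.
#' @export
count_occurrences <- function(subseq, region, max_mismatch = 0) {
  Biostrings::countPattern(
    subseq, Biostrings::DNAString(as_seq(region)),
    max.mismatch = max_mismatch, with.indels = FALSE
  )
}

#' Oligo placement constraints
#'
#' Primer and probe lengths default to the middle of the ranges used by the
#' published assay panel (primers 18-27 nt, probes 20-24 nt). Melting
#' temperature is deliberately not modelled.
#'
#' @param primer_length,probe_length lengths actually used, nt.
#' @param primer_range,probe_range admissible ranges, nt.
#' @param nested_gap gap between the forward primer end and the nested
#'   primer start, nt.
#' @param probe_gap minimum gap between the nested primer end and the probe
#'   footprint, nt.
#' @return a list of constraints.
#' @export
oligo_constraints <- function(primer_length = 20, probe_length = 20,
                              primer_range = c(18, 27), probe_range = c(20, 24),
                              nested_gap = 2, probe_gap = 1) {
  stopifnot(
    primer_length >= primer_range[1], primer_length <= primer_range[2],
    probe_length >= probe_range[1], probe_length <= probe_range[2]
  )
  list(
    primer_length = as.integer(primer_length),
    probe_length = as.integer(probe_length),
    primer_range = as.integer(primer_range),
    probe_range = as.integer(probe_range),
    nested_gap = as.integer(nested_gap),
    probe_gap = as.integer(probe_gap)
  )
}

#' Design the four oligos for one tag
#'
#' Geometry on the top strand, 0-based half-open: the forward primer sits at
#' the tag start; the nested primer is internal to the forward-amplified
#' span in the same orientation; the probe is internal and close to the
#' nested primer but reverse-oriented (it hybridises to the single-stranded
#' product of the nested primer); the reverse primer is the reverse
#' complement of the tag's final bases. The probe footprint is chosen so the
#' template base immediately 5' of it (the base templating single-base
#' extension at the probe 3' end) is A or G — A templates the ddUTP/Cy3
#' channel, G the ddCTP/Cy5 channel.
#'
#' @param tag a one-row tag tibble (from [select_tags()]) or a list with
#'   `name`, `start`, `end`.
#' @param region the [annotated_region()] the tag was selected from.
#' @param constraints an [oligo_constraints()] list.
#' @return a one-row tibble: `tag`, `tag_start`, `tag_end`, `forward`,
#'   `reverse`, `nested`, `probe`, `probe_start`, `extension_base`.
#' @export
design_oligos <- function(tag, region, constraints = oligo_constraints()) {
  s <- as.integer(tag$start)
  e <- as.integer(tag$end)
  seq <- as_seq(region)
  lf <- constraints$primer_length
  ln <- constraints$primer_length
  lr <- constraints$primer_length
  lp <- constraints$probe_length
  min_len <- lf + constraints$nested_gap + ln + constraints$probe_gap + lp + lr
  if (e - s < min_len) {
    abort(sprintf("tag %s too short for oligo placement", tag$name),
      class = "ighv_design_error"
    )
  }
  fwd <- seq_window(seq, s, s + lf)
  n_start <- s + lf + constraints$nested_gap
  nested <- seq_window(seq, n_start, n_start + ln)
  rev <- revcomp(seq_window(seq, e - lr, e))

  p <- n_start + ln + constraints$probe_gap
  probe <- NULL
  while (p + lp <= e) {
    ext <- substr(seq, p, p) # template base at 0-based position p - 1
    if (ext %in% c("A", "G")) {
      probe <- revcomp(seq_window(seq, p, p + lp))
      break
    }
    p <- p + 1L
  }
  if (is.null(probe)) {
    abort(
      sprintf("tag %s: no probe placement with an A/G extension template base", tag$name),
      class = "ighv_design_error"
    )
  }
  tibble(
    tag = tag$name, tag_start = s, tag_end = e,
    forward = fwd, reverse = rev, nested = nested, probe = probe,
    probe_start = as.integer(p), extension_base = substr(seq, p, p)
  )
}

#' Design oligo sets for a whole tag panel
#'
#' Tags for which no placement satisfies the extension-base rule are dropped
#' with a warning.
#'
#' @inheritParams design_oligos
#' @param tags a tag tibble from [select_tags()].
#' @return a tibble with one oligo-set row per designable tag.
#' @export
design_tag_panel <- function(tags, region, constraints = oligo_constraints()) {
  rows <- map(seq_len(nrow(tags)), function(i) {
    tryCatch(
      design_oligos(tags[i, ], region, constraints),
      ighv_design_error = function(cnd) {
        warn(sprintf("oligo design failed for tag %s", tags$name[i]))
        NULL
      }
    )
  })
  bind_rows(rows)
}

#' Longest complementary 3'-suffix score between two oligos
#'
#' The score is the largest k such that the last k bases of `x` are the
#' reverse complement of the last k bases of `y` — the two 3' ends annealing
#' perfectly over k bp, the configuration that seeds primer-dimer extension.
#' @noRd
comp_suffix_score <- function(x, y) {
  kmax <- min(nchar(x), nchar(y))
  for (k in kmax:1) {
    sx <- substr(x, nchar(x) - k + 1L, nchar(x))
    sy <- substr(y, nchar(y) - k + 1L, nchar(y))
    if (sx == revcomp(sy)) {
      return(k)
    }
  }
  0L
}

#' Screen a multiplex oligo panel for 3'-end complementarity conflicts
#'
#' Every unordered pair of primers (including an oligo against itself, which
#' flags palindromic 3' ends) is scored by its longest perfectly
#' complementary 3'-suffix; pairs scoring at or above `threshold` are
#' reported. Reporting is symmetric: each unordered pair appears once.
#'
#' @param oligos an oligo-set tibble from [design_tag_panel()], or any tibble
#'   with columns `id` and `seq`.
#' @param threshold minimum complementary-suffix length reported.
#' @param roles which oligo roles to screen (probes are not in the PCR mix).
#' @return a tibble `oligo_a`, `oligo_b`, `score`.
#' @export
check_compatibility <- function(oligos, threshold = 4,
                                roles = c("forward", "reverse", "nested")) {
  long <- if (all(c("id", "seq") %in% names(oligos))) {
    dplyr::select(oligos, "id", "seq")
  } else {
    pivot_longer(
      dplyr::select(oligos, "tag", dplyr::all_of(roles)),
      cols = dplyr::all_of(roles), names_to = "role", values_to = "seq"
    ) |>
      mutate(id = paste(.data$tag, .data$role, sep = ":")) |>
      dplyr::select("id", "seq")
  }
  n <- nrow(long)
  if (n == 0) {
    return(tibble(oligo_a = character(), oligo_b = character(), score = integer()))
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      sc <- comp_suffix_score(long$seq[i], long$seq[j])
      if (sc >= threshold) {
        out[[base::length(out) + 1L]] <- tibble(
          oligo_a = long$id[i], oligo_b = long$id[j], score = as.integer(sc)
        )
      }
    }
  }
  if (base::length(out)) bind_rows(out) else {
    tibble(oligo_a = character(), oligo_b = character(), score = integer())
  }
}
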