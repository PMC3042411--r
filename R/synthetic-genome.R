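#' Build a gene-segment template
#'
#' @param name gene-segment name (field convention: family-position, with a
#'   trailing "P" for pseudogenes, e.g. `"3-30"`, `"4-28.1P"`).
#' @param seq template nucleotide sequence.
#' @param exons a two-column matrix/data frame of 0-based half-open exon
#'   spans, relative to the template start.
#' @param functional logical; `FALSE` marks a pseudogene template.
#' @return a `gene_template` list.
#' @export
gene_template <- function(name, seq, exons, functional = TRUE) {
  exons <- as.data.frame(exons)
  names(exons) <- c("start", "end")
  stopifnot(all(exons$start < exons$end), all(exons$end <= nchar(seq)))
  structure(
    list(name = name, seq = toupper(seq), exons = exons, functional = functional),
    class = "gene_template"
  )
}

#' Generate a random V-segment-like template
#'
#' Two exons separated by an intron, mimicking the leader + V-exon layout of
#' IGHV segments. The concatenated exons form an open reading frame (ATG
#' followed by sense codons) for functional templates; pseudogene templates
#' carry one internal stop codon.
#'
#' @param name gene-segment name.
#' @param exon1,intron,exon2 part lengths in bp; `exon1 + exon2` must be a
#'   multiple of 3.
#' @param functional logical; `FALSE` plants a premature stop.
#' @param seed optional integer seed.
#' @return a `gene_template`.
#' @export
random_gene_template <- function(name, exon1 = 69, intron = 120, exon2 = 291,
                                 functional = TRUE, seed = NULL) {
  stopifnot((exon1 + exon2) %% 3 == 0)
  with_seed_(seed, {
    n_codon <- (exon1 + exon2) / 3
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    coding <- c("ATG", sample(setdiff(sense, "ATG"), n_codon - 1, replace = TRUE))
    if (!functional) {
      coding[ceiling(n_codon / 2)] <- sample(c("TAA", "TAG", "TGA"), 1)
    }
    coding <- paste(coding, collapse = "")
    seq <- paste0(
      substr(coding, 1, exon1), random_dna(intron),
      substr(coding, exon1 + 1, exon1 + exon2)
    )
    gene_template(
      name, seq,
      exons = rbind(
        c(0L, exon1),
        c(exon1 + intron, exon1 + intron + exon2)
      ),
      functional = functional
    )
  })
}

#' Build an ancestral region with gene segments at pseudo-random spacings
#'
#' Gene templates are placed left to right, non-overlapping, separated by
#' uniform-composition spacer sequence. Deterministic for a fixed seed.
#'
#' @param length total region length in bp.
#' @param gene_templates a list of [gene_template()] objects.
#' @param seed optional integer seed.
#' @param min_spacer minimum spacer between (and flanking) gene segments, bp.
#' @param name region name.
#' @return an [annotated_region()] with `gene_segment` and `exon` features.
#' @export
build_ancestral_region <- function(length, gene_templates, seed = NULL,
                                   min_spacer = 100, name = "synthetic_region") {
  lens <- map_int(gene_templates, function(t) nchar(t$seq))
  n <- base::length(gene_templates)
  needed <- sum(lens) + (n + 1L) * min_spacer
  if (length < needed) {
    abort(
      sprintf("region length %d too small: %d bp needed", length, needed),
      class = "ighv_sizing_error"
    )
  }
  with_seed_(seed, {
    extra <- length - needed
    extra_alloc <- if (extra > 0) {
      tabulate(sample.int(n + 1L, extra, replace = TRUE), nbins = n + 1L)
    } else {
      rep(0L, n + 1L)
    }
    spacers <- min_spacer + extra_alloc
    pieces <- character(0)
    feats <- list()
    pos <- 0L
    for (i in seq_len(n)) {
      pieces <- c(pieces, random_dna(spacers[i]))
      pos <- pos + spacers[i]
      t <- gene_templates[[i]]
      pieces <- c(pieces, t$seq)
      feats[[base::length(feats) + 1L]] <- tibble(
        kind = "gene_segment", start = pos, end = pos + nchar(t$seq),
        name = t$name, strand = "+", functional = t$functional, parent = NA_character_
      )
      for (j in seq_len(nrow(t$exons))) {
        feats[[base::length(feats) + 1L]] <- tibble(
          kind = "exon",
          start = pos + t$exons$start[j], end = pos + t$exons$end[j],
          name = paste0(t$name, "_exon", j), strand = "+",
          functional = NA, parent = t$name
        )
      }
      pos <- pos + nchar(t$seq)
    }
    pieces <- c(pieces, random_dna(spacers[n + 1L]))
    annotated_region(name, paste(pieces, collapse = ""), bind_rows(feats))
  })
}

#' Specification of a tandem duplication to plant
#'
#' @param n_complete number of complete tandem copies.
#' @param partial_length length of the trailing truncated copy, bp; must be
#'   shorter than the unit.
#' @param per_copy_divergence substitution fraction applied independently to
#'   every emitted copy, in `[0, 1)`. Two copies each mutated at rate `r`
#'   differ pairwise at about `2r` of their sites.
#' @param unit_length optional unit length in bp (filled in from the unit
#'   span by [plant_duplication()]).
#' @param seed optional integer seed.
#' @return a `duplication_spec` list.
#' @export
duplication_spec <- function(n_complete = 2, partial_length = 1000,
                             per_copy_divergence = 0.022,
                             unit_length = NA_integer_, seed = NULL) {
  if (per_copy_divergence < 0 || per_copy_divergence >= 1) {
    abort("per_copy_divergence must be in [0, 1)", class = "ighv_parameter_error")
  }
  if (!is.na(unit_length) && partial_length >= unit_length) {
    abort("partial_length must be shorter than the unit", class = "ighv_parameter_error")
  }
  structure(
    list(
      unit_length = unit_length, n_complete = as.integer(n_complete),
      partial_length = as.integer(partial_length),
      per_copy_divergence = per_copy_divergence, seed = seed
    ),
    class = "duplication_spec"
  )
}

#' Plant a tandem segmental duplication into a region
#'
#' Replaces the unit span with `n_complete` complete tandem copies followed
#' by one truncated copy (`partial_length` bp prefix of the unit). Every
#' copy is independently mutated at `per_copy_divergence`; gene-segment and
#' exon features inside the unit are replicated per copy and renamed with a
#' copy suffix; each copy is annotated with a `repeat_unit` feature named
#' after its (Roman-numbered) copy. Features straddling the unit borders are
#' dropped with a warning.
#'
#' @param region an [annotated_region()].
#' @param unit_span length-2 integer vector, the 0-based half-open unit span.
#' @param spec a [duplication_spec()].
#' @return a new [annotated_region()].
#' @export
plant_duplication <- function(region, unit_span, spec) {
  s <- as.integer(unit_span[1])
  e <- as.integer(unit_span[2])
  len <- region_length(region)
  if (s < 0 || e > len || s >= e) {
    abort("unit_span outside region", class = "ighv_interval_error")
  }
  L <- e - s
  if (spec$partial_length >= L) {
    abort("partial_length must be shorter than the unit", class = "ighv_parameter_error")
  }
  spec$unit_length <- L
  unit <- seq_window(region$seq, s, e)

  copies <- with_seed_(spec$seed, {
    cc <- map(seq_len(spec$n_complete), function(k) {
      mutate_seq(unit, spec$per_copy_divergence)
    })
    pp <- mutate_seq(
      substr(unit, 1L, spec$partial_length), spec$per_copy_divergence
    )
    c(cc, list(pp))
  })

  f <- region$features
  inside <- f$start >= s & f$end <= e
  before <- f$end <= s
  after <- f$start >= e
  straddle <- !(inside | before | after)
  if (any(straddle)) {
    warn(paste0(
      "dropping features straddling the unit border: ",
      paste(f$name[straddle], collapse = ", ")
    ))
  }

  delta <- (spec$n_complete - 1L) * L + spec$partial_length
  new_feats <- list(f[before, ], shift_features_after(f[after, ], e, delta))
  unit_feats <- dplyr::mutate(f[inside, ], start = .data$start - s, end = .data$end - s)
  n_copies <- spec$n_complete + 1L
  for (k in seq_len(n_copies)) {
    offset <- s + (k - 1L) * L
    copy_len <- if (k <= spec$n_complete) L else spec$partial_length
    keep <- unit_feats[unit_feats$end <= copy_len, ]
    if (nrow(keep)) {
      keep <- dplyr::mutate(
        keep,
        start = .data$start + offset, end = .data$end + offset,
        name = paste0(.data$name, ".", k),
        parent = ifelse(is.na(.data$parent), .data$parent, paste0(.data$parent, ".", k))
      )
      new_feats[[base::length(new_feats) + 1L]] <- keep
    }
    new_feats[[base::length(new_feats) + 1L]] <- tibble(
      kind = "repeat_unit", start = offset, end = offset + copy_len,
      name = paste0("repeat_", as.character(utils::as.roman(k))),
      strand = "+", functional = NA, parent = NA_character_
    )
  }

  new_seq <- paste0(
    seq_window(region$seq, 0L, s),
    paste(map_chr(copies, "seq"), collapse = ""),
    seq_window(region$seq, e, len)
  )
  annotated_region(region$name, new_seq, drop_orphan_exons(bind_rows(new_feats)))
}

#' Mutate a sequence by random substitutions
#'
#' The number of substitutions is binomial in the sequence length; positions
#' are uniform without replacement and the replacement base always differs
#' from the original, so the reported count equals the Hamming distance to
#' the input.
#'
#' @param seq nucleotide sequence.
#' @param sub_rate per-base substitution probability, in `[0, 1)`.
#' @param seed optional integer seed; `NULL` draws from the current stream.
#' @return a list with `seq`, `n_substitutions` and 0-based `positions`.
#' @export
#' @examples
#' mutate_seq("ACGTACGT", 0.25, seed = 1)
mutate_seq <- function(seq, sub_rate, seed = NULL) {
  if (sub_rate < 0 || sub_rate >= 1) {
    abort("sub_rate must be in [0, 1)", class = "ighv_parameter_error")
  }
  n <- nchar(seq)
  with_seed_(seed, {
    k <- rbinom(1L, n, sub_rate)
    if (k == 0L) {
      return(list(seq = seq, n_substitutions = 0L, positions = integer(0)))
    }
    pos <- sort(sample.int(n, k))
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[pos] <- map_chr(chars[pos], function(b) sample(setdiff(DNA_BASES, b), 1))
    list(
      seq = paste(chars, collapse = ""),
      n_substitutions = as.integer(k),
      positions = pos - 1L
    )
  })
}

#' Per-haplotype edit specification for a donor
#'
#' @param delete_units integer indices (1-based, in genomic order) of
#'   `repeat_unit` copies to delete.
#' @param extra_divergence additional substitution fraction applied across
#'   the remaining repeat-unit spans, emulating haplotype-private divergence
#'   that can render tags undetectable without any deletion.
#' @return a `variant_spec` list.
#' @export
variant_spec <- function(delete_units = integer(0), extra_divergence = 0) {
  structure(
    list(delete_units = as.integer(delete_units), extra_divergence = extra_divergence),
    class = "variant_spec"
  )
}

#' Derive a donor's two haplotypes from a reference region
#'
#' Each haplotype starts from the reference, has `extra_divergence` applied
#' over its repeat-unit spans, then loses the repeat copies listed in
#' `delete_units` (downstream feature coordinates shift consistently).
#'
#' @param region an [annotated_region()] (typically the duplicated reference).
#' @param variant_specs list of two [variant_spec()] objects (H1, H2).
#' @param seed optional integer seed.
#' @param donor donor label used to name the haplotypes.
#' @return a list of two [annotated_region()] objects named `H1`, `H2`.
#' @export
make_donor_haplotypes <- function(region, variant_specs, seed = NULL, donor = region$name) {
  stopifnot(base::length(variant_specs) == 2)
  with_seed_(seed, {
    haps <- map(1:2, function(i) {
      h <- apply_variant(region, variant_specs[[i]])
      h$name <- paste0(donor, "_H", i)
      h
    })
    names(haps) <- c("H1", "H2")
    haps
  })
}

#' @noRd
apply_variant <- function(region, vs) {
  h <- region
  units <- region_features(h, "repeat_unit")
  units <- units[order(units$start), ]
  if (base::length(vs$delete_units) &&
    any(vs$delete_units < 1L | vs$delete_units > nrow(units))) {
    abort("delete_units refers to a repeat copy that is not present",
      class = "ighv_spec_error"
    )
  }
  if (vs$extra_divergence > 0 && nrow(units)) {
    chars <- strsplit(h$seq, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(units))) {
      span <- seq_window(h$seq, units$start[i], units$end[i])
      m <- mutate_seq(span, vs$extra_divergence)
      chars[(units$start[i] + 1L):units$end[i]] <- strsplit(m$seq, "", fixed = TRUE)[[1]]
    }
    h$seq <- paste(chars, collapse = "")
  }
  for (idx in sort(vs$delete_units, decreasing = TRUE)) {
    u <- units[idx, ]
    f <- h$features
    inside <- f$start >= u$start & f$end <= u$end
    keep <- f[!inside, ]
    straddle <- keep$start < u$end & keep$end > u$start
    if (any(straddle)) {
      warn("dropping features straddling a deleted repeat copy")
      keep <- keep[!straddle, ]
    }
    keep <- shift_features_after(keep, u$end, -(u$end - u$start))
    h$seq <- paste0(
      seq_window(h$seq, 0L, u$start),
      seq_window(h$seq, u$end, nchar(h$seq))
    )
    h$features <- drop_orphan_exons(keep)
  }
  validate_region(h)
  h
}
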