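#' Phase a sperm panel into two parental haplotypes
#'
#' Sperm are partitioned into two clusters by similarity of their binary
#' call vectors: the two most dissimilar sperm seed the clusters, and
#' nearest-centroid reassignment runs to convergence. Per-tag consensus per
#' cluster is `+` when at least `consensus_frac` of its assigned sperm
#' detected the tag, `ud` when at least `consensus_frac` did not, and `-`
#' (unresolved) otherwise. Allelic sequences segregate into different
#' gametes, so the two cluster consensuses are the two parental haplotypes.
#'
#' A bipartition only stands when it is better than a single cluster: each
#' cluster must hold at least `min_support` sperm, and at least one tag on
#' which the cluster consensuses disagree must segregate at an
#' intermediate overall rate (`segregation_band`) — a genuinely
#' heterozygous tag is transmitted to close to half the gametes, whereas
#' apparent differences driven by assay noise sit near 0 or 1. Otherwise
#' both haplotypes report the common consensus pattern.
#'
#' @param gm a `sperm_genotypes` tibble from [simulate_sperm_panel()], or
#'   any tibble with columns `sperm_id`, `tag`, `call`.
#' @param min_support minimum sperm per cluster for a split to stand.
#' @param consensus_frac consensus threshold in `(0.5, 1]`.
#' @param segregation_band overall detected-fraction interval within which
#'   a discordant tag counts as genuinely segregating.
#' @return a `sperm_phasing` object: list with `haplotypes` (tibble
#'   `haplotype`, `tag`, `status`, `n_detected`, `n_assigned`),
#'   `assignments` (tibble `sperm_id`, `haplotype`), `donor`, `separated`,
#'   `n_iter`.
#' @export
phase_sperm <- function(gm, min_support = 5, consensus_frac = 0.7,
                        segregation_band = c(0.2, 0.8)) {
  tags <- attr(gm, "tags") %||% unique(gm$tag)
  donor <- attr(gm, "donor") %||% "donor"
  wide <- pivot_wider(
    as_tibble(gm)[, c("sperm_id", "tag", "call")],
    names_from = "tag", values_from = "call"
  )
  x <- as.matrix(wide[, tags]) == "detected"
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2 * min_support) {
    abort("too few sperm to phase (need at least 2 * min_support)",
      class = "ighv_insufficient_data_error"
    )
  }

  d <- as.matrix(stats::dist(x, method = "manhattan"))
  seed_pair <- arrayInd(which.max(d), dim(d))
  centroids <- x[c(seed_pair[1], seed_pair[2]), , drop = FALSE]
  assign <- rep(1L, n)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    d1 <- rowSums(sweep(x, 2, centroids[1, ])^2)
    d2 <- rowSums(sweep(x, 2, centroids[2, ])^2)
    new_assign <- ifelse(d2 < d1, 2L, 1L)
    if (all(new_assign == assign) && n_iter > 1L) break
    assign <- new_assign
    for (k in 1:2) {
      if (any(assign == k)) {
        centroids[k, ] <- colMeans(x[assign == k, , drop = FALSE])
      }
    }
    if (n_iter >= 100L) break
  }

  # label symmetry broken deterministically: the first sperm's cluster is H1
  if (assign[1] == 2L) assign <- 3L - assign

  sizes <- tabulate(assign, 2L)
  separated <- all(sizes >= min_support)
  if (separated) {
    # a split must be anchored by at least one genuinely segregating tag
    f1 <- colMeans(x[assign == 1L, , drop = FALSE])
    f2 <- colMeans(x[assign == 2L, , drop = FALSE])
    overall <- colMeans(x)
    discordant <- (f1 >= consensus_frac & f2 <= 1 - consensus_frac) |
      (f2 >= consensus_frac & f1 <= 1 - consensus_frac)
    segregating <- overall >= segregation_band[1] & overall <= segregation_band[2]
    separated <- any(discordant & segregating)
  }
  consensus <- function(rows) {
    sub <- x[rows, , drop = FALSE]
    frac <- colMeans(sub)
    tibble(
      tag = tags,
      status = dplyr::case_when(
        frac >= consensus_frac ~ "+",
        frac <= 1 - consensus_frac ~ "ud",
        TRUE ~ "-"
      ),
      n_detected = as.integer(colSums(sub)),
      n_assigned = nrow(sub)
    )
  }
  haplotypes <- if (separated) {
    bind_rows(
      mutate(consensus(assign == 1L), haplotype = "H1"),
      mutate(consensus(assign == 2L), haplotype = "H2")
    )
  } else {
    common <- consensus(rep(TRUE, n))
    bind_rows(
      mutate(common, haplotype = "H1"),
      mutate(common, haplotype = "H2")
    )
  }
  structure(
    list(
      haplotypes = dplyr::select(
        haplotypes, "haplotype", "tag", "status", "n_detected", "n_assigned"
      ),
      assignments = tibble(
        sperm_id = wide$sperm_id, haplotype = paste0("H", assign)
      ),
      donor = donor, separated = separated, n_iter = n_iter, tags = tags
    ),
    class = "sperm_phasing"
  )
}

#' @export
print.sperm_phasing <- function(x, ...) {
  cat(sprintf(
    "<sperm_phasing> donor %s: %d sperm, %d tags, clusters %s\n",
    x$donor, nrow(x$assignments), base::length(x$tags),
    if (x$separated) "separated" else "merged (common pattern)"
  ))
  wide <- pivot_wider(
    x$haplotypes[, c("haplotype", "tag", "status")],
    names_from = "haplotype", values_from = "status"
  )
  print(wide, n = base::length(x$tags))
  invisible(x)
}

#' @describeIn phase_sperm tidy method: the per-tag haplotype call table.
#' @param x a `sperm_phasing` object.
#' @param ... unused.
#' @export
tidy.sperm_phasing <- function(x, ...) {
  mutate(x$haplotypes, donor = x$donor, .before = 1)
}

#' @describeIn phase_sperm glance method: one-row phasing summary.
#' @export
glance.sperm_phasing <- function(x, ...) {
  wide <- pivot_wider(
    x$haplotypes[, c("haplotype", "tag", "status")],
    names_from = "haplotype", values_from = "status"
  )
  tibble(
    donor = x$donor,
    n_sperm = nrow(x$assignments),
    n_tags = base::length(x$tags),
    n_discordant_tags = sum(wide$H1 != wide$H2),
    separated = x$separated,
    n_iter = x$n_iter
  )
}

#' Classify tags across a collection of haplotype calls
#'
#' A tag undetected (`ud` or `-`) in every haplotype is
#' `undetectable_in_all`; a tag detected in every haplotype is
#' `non_polymorphic_detected`; a tag whose detected status varies is
#' `polymorphic`. Unresolved `-` calls count as "not detected", but remain
#' distinct in the underlying call table.
#'
#' @param calls a tibble of haplotype calls with columns `tag`, `status` and
#'   identifying columns `donor` and/or `haplotype` (at least two distinct
#'   haplotype columns overall are required).
#' @param tag_order optional character vector fixing the tag order.
#' @return a tibble `tag`, `class` in genomic (or given) order.
#' @export
classify_tags <- function(calls, tag_order = NULL) {
  id_cols <- intersect(c("donor", "haplotype"), names(calls))
  if (base::length(id_cols) == 0) {
    abort("calls must carry donor and/or haplotype identifier columns",
      class = "ighv_parameter_error"
    )
  }
  calls <- mutate(calls, .column = do.call(paste, c(calls[id_cols], sep = "/")))
  if (dplyr::n_distinct(calls$.column) < 2) {
    abort("tag classification needs at least two haplotypes",
      class = "ighv_insufficient_data_error"
    )
  }
  tag_order <- tag_order %||% unique(calls$tag)
  out <- calls |>
    mutate(detected = .data$status == "+") |>
    group_by(.data$tag) |>
    summarise(
      class = dplyr::case_when(
        all(.data$detected) ~ "non_polymorphic_detected",
        all(!.data$detected) ~ "undetectable_in_all",
        TRUE ~ "polymorphic"
      ),
      .groups = "drop"
    )
  out[match(tag_order, out$tag), ]
}

#' Maximal runs of consecutively undetectable tags in one haplotype
#'
#' Scans the full ordered tag list of a single haplotype's calls; `ud` and
#' `-` both count as undetectable. Runs of any length are returned; filter
#' on `length >= 2` for the consecutive-undetectable criterion.
#'
#' @param calls a tibble with columns `tag`, `status` for one haplotype.
#' @param tag_order optional character vector fixing the tag order.
#' @return a tibble `start_tag`, `end_tag`, `length`.
#' @export
find_undetectable_runs <- function(calls, tag_order = NULL) {
  tag_order <- tag_order %||% unique(calls$tag)
  status <- calls$status[match(tag_order, calls$tag)]
  und <- status %in% c("ud", "-")
  r <- rle(und)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(
    start_tag = tag_order[starts[keep]],
    end_tag = tag_order[ends[keep]],
    length = r$lengths[keep]
  )
}

#' Delimit the polymorphic region and its detected flanks
#'
#' The minimal tag interval containing every polymorphic tag, plus the
#' nearest flanking tags that are detected and non-polymorphic in all
#' haplotypes.
#'
#' @param classes a tibble `tag`, `class` from [classify_tags()], in
#'   genomic order.
#' @return a one-row tibble `first_tag`, `last_tag`, `n_polymorphic`,
#'   `flank_left`, `flank_right`; zero rows when no tag is polymorphic.
#' @export
delimit_polymorphic_region <- function(classes) {
  poly <- which(classes$class == "polymorphic")
  if (base::length(poly) == 0) {
    return(tibble(
      first_tag = character(), last_tag = character(),
      n_polymorphic = integer(), flank_left = character(), flank_right = character()
    ))
  }
  det <- which(classes$class == "non_polymorphic_detected")
  left <- det[det < min(poly)]
  right <- det[det > max(poly)]
  tibble(
    first_tag = classes$tag[min(poly)],
    last_tag = classes$tag[max(poly)],
    n_polymorphic = base::length(poly),
    flank_left = if (base::length(left)) classes$tag[max(left)] else NA_character_,
    flank_right = if (base::length(right)) classes$tag[min(right)] else NA_character_
  )
}
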