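#' Configuration for the end-to-end synthetic analysis pipeline
#'
#' Defaults emulate the study region this package models: an ancestral
#' segment carrying a row of V gene segments, a ~24.5 kb unit duplicated
#' into two complete tandem copies plus a ~1 kb truncated copy (copies
#' ~4.4% diverged pairwise), six sperm donors whose haplotypes differ by
#' repeat-copy deletion and haplotype-private divergence, tag selection at
#' ~5 kb spacing, and panels of 49-60 sperm per donor. Smaller values of
#' `ancestral_length`/`unit_length` scale every stage down proportionally.
#'
#' @param ancestral_length ancestral region length, bp.
#' @param n_genes number of gene-segment templates placed.
#' @param unit_length duplication unit length, bp.
#' @param n_complete complete tandem copies.
#' @param partial_length truncated-copy length, bp.
#' @param per_copy_divergence substitution fraction per planted copy.
#' @param donor_specs named list (one entry per donor) of lists of two
#'   [variant_spec()]s; `NULL` uses six default donors.
#' @param spacing,tag_length tag selection parameters, bp.
#' @param noise a [noise_model()] (its seed is ignored; stage seeds derive
#'   from `master_seed`).
#' @param rules a [detection_rules()] list.
#' @param dotplot a [dot_params()] list.
#' @param min_unit minimum repeat unit considered at block discovery, bp.
#' @param n_sperm sperm per donor; `NULL` draws 49-60 per donor.
#' @param clock a [clock_params()] list.
#' @param master_seed integer master seed; each stage derives its own
#'   sub-seed from it by stage-name hashing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(ancestral_length = 40000, n_genes = 10,
                            unit_length = 24500, n_complete = 2,
                            partial_length = 1000, per_copy_divergence = 0.022,
                            donor_specs = NULL,
                            spacing = 5000, tag_length = 160,
                            noise = noise_model(),
                            rules = detection_rules(),
                            dotplot = dot_params(),
                            min_unit = NULL,
                            n_sperm = NULL,
                            clock = clock_params(),
                            master_seed = 1L) {
  donor_specs <- donor_specs %||% default_donor_specs()
  structure(
    list(
      ancestral_length = ancestral_length, n_genes = n_genes,
      unit_length = unit_length, n_complete = n_complete,
      partial_length = partial_length, per_copy_divergence = per_copy_divergence,
      donor_specs = donor_specs, spacing = spacing, tag_length = tag_length,
      noise = noise, rules = rules, dotplot = dotplot,
      min_unit = min_unit %||% floor(unit_length / 3),
      n_sperm = n_sperm, clock = clock, master_seed = as.integer(master_seed)
    ),
    class = "pipeline_config"
  )
}

#' Six default donors spanning the observed haplotype topologies
#'
#' Intact homozygous donors, a donor missing one and both complete copies,
#' a deletion on a diverged background, and a donor with haplotype-private
#' divergence only — the configurations seen among phased haplotypes of
#' the region.
#'
#' @return a named list of per-donor lists of two [variant_spec()]s.
#' @export
default_donor_specs <- function() {
  list(
    D01 = list(variant_spec(), variant_spec()),
    D02 = list(
      variant_spec(delete_units = c(1, 2)),
      variant_spec(delete_units = 1)
    ),
    D03 = list(variant_spec(), variant_spec()),
    D04 = list(
      variant_spec(),
      variant_spec(delete_units = 2, extra_divergence = 0.02)
    ),
    D05 = list(variant_spec(), variant_spec()),
    D06 = list(variant_spec(extra_divergence = 0.015), variant_spec())
  )
}

#' Pick a duplication unit span that does not cut a gene segment
#' @noRd
choose_unit_span <- function(region, unit_length, margin = 200) {
  genes <- region_features(region, "gene_segment")
  genes <- genes[order(genes$start), ]
  len <- region_length(region)
  cuts <- function(pos) any(genes$start < pos & genes$end > pos)
  for (k in seq_len(nrow(genes))) {
    s <- genes$start[k] - margin
    e <- s + unit_length
    if (s >= 0 && e <= len && !cuts(s) && !cuts(e)) {
      return(c(s, e))
    }
  }
  abort("no unit span of the requested length avoids cutting a gene segment",
    class = "ighv_sizing_error"
  )
}

#' Extract gene-segment sequences from a region
#'
#' @param region an [annotated_region()].
#' @return a tibble `name`, `functional`, `seq`.
#' @export
gene_sequences <- function(region) {
  g <- region_features(region, "gene_segment")
  tibble(
    name = g$name, functional = g$functional,
    seq = map_chr(seq_len(nrow(g)), function(i) {
      seq_window(region$seq, g$start[i], g$end[i])
    })
  )
}

#' @noRd
run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "ighv_stage_error"
    )
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> tag design -> sperm assay -> phasing ->
#' classification/delimitation -> duplicate-block discovery -> divergence
#' accounting -> mutational clock, writing every table under `out_dir` and
#' returning a manifest of outputs with stage provenance. Fully
#' deterministic for a fixed `master_seed`.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return a `pipeline_result` list: `manifest` (tibble `file`, `stage`),
#'   `region`, `haplotypes`, `tags`, `oligos`, `phasings`, `classes`,
#'   `runs`, `region_delim`, `blocks`, `divergence`, `clock`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("ighvdup_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(file, stage) {
    manifest[[base::length(manifest) + 1L]] <<- tibble(file = file, stage = stage)
    file.path(out_dir, file)
  }

  ## -- simulate ------------------------------------------------------------
  region <- run_stage("simulate", {
    templates <- with_seed_(stage_seed(cfg$master_seed, "templates"), {
      map(seq_len(cfg$n_genes), function(i) {
        random_gene_template(
          sprintf("g%02d", i),
          functional = i %% 3L != 0L # every third template is a pseudogene
        )
      })
    })
    anc <- build_ancestral_region(
      cfg$ancestral_length, templates,
      seed = stage_seed(cfg$master_seed, "ancestral")
    )
    span <- choose_unit_span(anc, cfg$unit_length)
    plant_duplication(
      anc, span,
      duplication_spec(
        n_complete = cfg$n_complete, partial_length = cfg$partial_length,
        per_copy_divergence = cfg$per_copy_divergence,
        seed = stage_seed(cfg$master_seed, "duplication")
      )
    )
  })
  haplotypes <- run_stage("simulate", {
    purrr::imap(cfg$donor_specs, function(specs, donor) {
      make_donor_haplotypes(
        region, specs,
        seed = stage_seed(cfg$master_seed, paste0("donor_", donor)),
        donor = donor
      )
    })
  })
  write_region_fasta(region, emit("reference.fasta", "simulate"))
  write_region_fasta(
    unlist(haplotypes, recursive = FALSE),
    emit("haplotypes.fasta", "simulate")
  )
  write_features_bed(region, emit("reference_features.bed", "simulate"))

  ## -- tag design ----------------------------------------------------------
  tags <- run_stage("design", {
    suppressWarnings(select_tags(
      region,
      spacing = cfg$spacing, tag_length = cfg$tag_length
    ))
  })
  oligos <- run_stage("design", design_tag_panel(tags, region))
  conflicts <- run_stage("design", check_compatibility(oligos))
  readr::write_tsv(tags, emit("tags.tsv", "design"))
  readr::write_tsv(oligos, emit("oligos.tsv", "design"))
  readr::write_tsv(conflicts, emit("primer_conflicts.tsv", "design"))

  ## -- sperm assay + phasing -----------------------------------------------
  phasings <- run_stage("phase", {
    purrr::imap(haplotypes, function(hp, donor) {
      nm <- noise_model(
        dropout = cfg$noise$dropout, false_positive = cfg$noise$false_positive,
        seed = stage_seed(cfg$master_seed, paste0("assay_", donor))
      )
      gm <- simulate_sperm_panel(
        hp, oligos,
        n_sperm = cfg$n_sperm, noise = nm, rules = cfg$rules, donor = donor
      )
      write_genotype_tsv(gm, emit(paste0("genotypes_", donor, ".tsv"), "assay"))
      phase_sperm(gm)
    })
  })
  calls <- bind_rows(map(phasings, tidy))
  write_haplotype_table_tsv(
    calls, emit("haplotype_table.tsv", "phase"),
    tag_order = tags$name
  )

  ## -- classification ------------------------------------------------------
  classes <- run_stage("classify", classify_tags(calls, tag_order = tags$name))
  runs <- run_stage("classify", {
    calls |>
      mutate(column = paste(.data$donor, .data$haplotype, sep = "/")) |>
      group_by(.data$column) |>
      dplyr::group_modify(function(d, g) find_undetectable_runs(d, tag_order = tags$name)) |>
      ungroup()
  })
  region_delim <- run_stage("classify", delimit_polymorphic_region(classes))
  readr::write_tsv(classes, emit("tag_classes.tsv", "classify"))
  readr::write_tsv(runs, emit("undetectable_runs.tsv", "classify"))
  readr::write_tsv(region_delim, emit("polymorphic_region.tsv", "classify"))

  ## -- duplicate blocks ----------------------------------------------------
  blocks <- run_stage("blocks", {
    find_repeat_units(region, cfg$dotplot, min_unit = cfg$min_unit)
  })
  readr::write_tsv(as_tibble(blocks), emit("repeat_blocks.tsv", "blocks"))

  ## -- divergence ----------------------------------------------------------
  divergence <- run_stage("diverge", {
    pairs <- bind_rows(
      paralog_pairs(region),
      allelic_pairs(haplotypes)
    )
    build_divergence_table(pairs)
  })
  readr::write_tsv(divergence$records, emit("divergence.tsv", "diverge"))
  readr::write_tsv(divergence$groups, emit("divergence_groups.tsv", "diverge"))

  ## -- clock ---------------------------------------------------------------
  clock <- run_stage("clock", {
    units <- region_features(region, "repeat_unit")
    units <- units[order(units$start), ]
    c1 <- seq_window(region$seq, units$start[1], units$end[1])
    c2 <- seq_window(region$seq, units$start[2], units$end[2])
    d <- hamming_str(c1, c2) / nchar(c1)
    clock_report(d, cfg$clock)
  })
  jsonlite::write_json(
    glance(clock), emit("clock.json", "clock"),
    auto_unbox = TRUE, digits = NA
  )

  manifest <- bind_rows(manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  structure(
    list(
      manifest = manifest, out_dir = out_dir,
      region = region, haplotypes = haplotypes, tags = tags, oligos = oligos,
      conflicts = conflicts, phasings = phasings, classes = classes,
      runs = runs, region_delim = region_delim, blocks = blocks,
      divergence = divergence, clock = clock
    ),
    class = "pipeline_result"
  )
}

#' Paralogous gene-segment pairs between successive repeat copies
#' @noRd
paralog_pairs <- function(region) {
  gs <- gene_sequences(region)
  gs <- gs[grepl("\\.\\d+$", gs$name), ]
  if (nrow(gs) == 0) {
    return(tibble(
      name_a = character(), seq_a = character(),
      name_b = character(), seq_b = character(), relation = character()
    ))
  }
  gs$base <- sub("\\.\\d+$", "", gs$name)
  gs$copy <- as.integer(sub("^.*\\.", "", gs$name))
  out <- list()
  for (b in unique(gs$base)) {
    g <- gs[gs$base == b, ]
    g <- g[order(g$copy), ]
    if (nrow(g) >= 2) {
      for (k in seq_len(nrow(g) - 1L)) {
        out[[base::length(out) + 1L]] <- tibble(
          name_a = g$name[k], seq_a = g$seq[k],
          name_b = g$name[k + 1L], seq_b = g$seq[k + 1L],
          relation = "paralogous"
        )
      }
    }
  }
  bind_rows(out)
}

#' Allelic gene-segment pairs between the two haplotypes of each donor
#' @noRd
allelic_pairs <- function(haplotypes) {
  out <- list()
  for (donor in names(haplotypes)) {
    g1 <- gene_sequences(haplotypes[[donor]]$H1)
    g2 <- gene_sequences(haplotypes[[donor]]$H2)
    shared <- intersect(g1$name, g2$name)
    shared <- shared[g1$seq[match(shared, g1$name)] != g2$seq[match(shared, g2$name)]]
    if (base::length(shared)) {
      out[[base::length(out) + 1L]] <- tibble(
        name_a = paste0(donor, "_H1:", shared),
        seq_a = g1$seq[match(shared, g1$name)],
        name_b = paste0(donor, "_H2:", shared),
        seq_b = g2$seq[match(shared, g2$name)],
        relation = "allelic"
      )
    }
  }
  if (base::length(out)) bind_rows(out) else {
    tibble(
      name_a = character(), seq_a = character(),
      name_b = character(), seq_b = character(), relation = character()
    )
  }
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %s: %d outputs across %d stages\n",
    x$out_dir, nrow(x$manifest), dplyr::n_distinct(x$manifest$stage)
  ))
  print(x$manifest, n = nrow(x$manifest))
  invisible(x)
}
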