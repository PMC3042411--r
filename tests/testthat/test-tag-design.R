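test_that("a ~90 kb region at 5 kb spacing yields the expected tag panel", {
  tpl <- withr::with_seed(20, {
    lapply(1:8, function(i) random_gene_template(paste0("g", i), seed = NULL))
  })
  region <- build_ancestral_region(90000, tpl, seed = 21)
  tags <- select_tags(region, spacing = 5000, tag_length = 160)

  expect_gte(nrow(tags), 17)
  expect_lte(nrow(tags), 18)
  expect_equal(tags$start, sort(tags$start))
  expect_false(any(duplicated(tags$name)))
  # non-coding: no overlap with any gene segment
  genes <- region_features(region, "gene_segment")
  for (k in seq_len(nrow(tags))) {
    expect_false(any(genes$start < tags$end[k] & genes$end > tags$start[k]))
  }
  # unique in the region
  for (k in seq_len(nrow(tags))) {
    w <- substr(region$seq, tags$start[k] + 1, tags$end[k])
    expect_equal(count_occurrences(w, region), 1)
  }
})

test_that("exact tandem repeats admit no tags and are skipped with warnings", {
  withr::with_seed(22, {
    unit <- random_seq(400)
    seq <- paste0(random_seq(1000), strrep(unit, 4), random_seq(1000))
  })
  region <- annotated_region("rep", seq)
  warnings <- testthat::capture_warnings(
    tags <- select_tags(region, spacing = 500, max_len = 225, tag_length = 150)
  )
  expect_true(any(grepl("no unique", warnings)))
  # no tag interval sits fully inside the repeated block
  inside <- tags$start >= 1000 & tags$end <= 1000 + 4 * 400
  expect_false(any(inside))
  expect_gt(length(attr(tags, "skipped")), 0)
})

test_that("count_occurrences agrees with the brute-force sliding-window oracle", {
  withr::with_seed(23, {
    region_seq <- random_seq(10000)
    for (rep in 1:10) {
      q <- random_seq(20)
      expect_equal(
        count_occurrences(q, region_seq, max_mismatch = 0),
        oracle_count_occurrences(q, region_seq, 0)
      )
    }
    # queries taken verbatim occur at least once; with mismatches too
    for (rep in 1:5) {
      p <- sample(0:(10000 - 25), 1)
      q <- substr(region_seq, p + 1, p + 25)
      expect_gte(count_occurrences(q, region_seq), 1)
      mm <- sample(0:2, 1)
      expect_equal(
        count_occurrences(q, region_seq, max_mismatch = mm),
        oracle_count_occurrences(q, region_seq, mm)
      )
    }
  })
  # a window from a zero-divergence duplicate occurs at least twice
  withr::with_seed(24, {
    anc <- annotated_region("r", random_seq(1200))
  })
  dup <- plant_duplication(
    anc, c(300, 700),
    duplication_spec(n_complete = 2, partial_length = 50, per_copy_divergence = 0, seed = 1)
  )
  w <- substr(dup$seq, 401, 430)
  expect_gte(count_occurrences(w, dup), 2)
})

test_that("oligo placement follows the forward/nested/probe/reverse geometry", {
  withr::with_seed(25, {
    region <- annotated_region("r", random_seq(600))
  })
  tag <- tibble::tibble(name = "VHS0", start = 100L, end = 260L)
  o <- design_oligos(tag, region)

  # nested primer lies within the forward-amplified span
  amplicon <- substr(region$seq, 101, 260)
  expect_true(grepl(o$nested, amplicon, fixed = TRUE))
  # probe is reverse-oriented: its reverse complement is on the top strand
  expect_true(grepl(revcomp(o$probe), amplicon, fixed = TRUE))
  # reverse primer is the reverse complement of the tag's final bases
  expect_identical(o$reverse, revcomp(substr(region$seq, 260 - 19, 260)))
  # extension-template base rule
  expect_true(o$extension_base %in% c("A", "G"))
  expect_identical(substr(region$seq, o$probe_start, o$probe_start), o$extension_base)
})

test_that("a tag with no A/G extension base in the probe window fails design", {
  withr::with_seed(26, {
    seq <- random_seq(300)
  })
  # make every feasible extension-base position C or T
  chars <- strsplit(seq, "")[[1]]
  chars[43:141] <- rep(c("C", "T"), length.out = 99)
  region <- annotated_region("r", paste(chars, collapse = ""))
  tag <- tibble::tibble(name = "VHS0", start = 0L, end = 160L)
  expect_error(design_oligos(tag, region), class = "ighv_design_error")
  # the panel wrapper downgrades the failure to a warning and drops the tag
  expect_warning(
    out <- design_tag_panel(tag, region),
    "design failed"
  )
  expect_equal(nrow(out), 0)
})

test_that("primer compatibility flags complementary 3' ends symmetrically", {
  # two primers whose 3'-terminal 5-mers anneal in antiparallel
  x <- paste0("ACGTACGTACGTACG", "GATCC")
  y <- paste0("TTTTTTTTTTTTTTT", revcomp("GATCC"))
  oligos <- tibble::tibble(id = c("x", "y"), seq = c(x, y))
  conf <- check_compatibility(oligos, threshold = 4)
  expect_equal(nrow(conf[conf$oligo_a == "x" & conf$oligo_b == "y", ]), 1)
  expect_equal(conf$score[conf$oligo_a == "x" & conf$oligo_b == "y"], 5)

  # a palindromic 3' end conflicts with itself
  p <- paste0("TTTTTTTTTTTT", "GAATTC")
  self <- check_compatibility(tibble::tibble(id = "p", seq = p), threshold = 4)
  expect_true(any(self$oligo_a == "p" & self$oligo_b == "p"))

  # empty input, empty output
  expect_equal(nrow(check_compatibility(tibble::tibble(id = character(), seq = character()))), 0)

  # symmetry: the score does not depend on argument order
  withr::with_seed(27, {
    for (rep in 1:20) {
      a <- random_seq(20)
      b <- random_seq(20)
      ab <- check_compatibility(tibble::tibble(id = c("a", "b"), seq = c(a, b)), threshold = 1)
      ba <- check_compatibility(tibble::tibble(id = c("b", "a"), seq = c(b, a)), threshold = 1)
      cross_ab <- ab$score[ab$oligo_a != ab$oligo_b]
      cross_ba <- ba$score[ba$oligo_a != ba$oligo_b]
      expect_identical(cross_ab, cross_ba)
    }
  })
})

test_that("tags stay unique in haplotypes that only delete repeat copies", {
  withr::with_seed(28, {
    anc <- annotated_region("r", random_seq(4000))
  })
  region <- plant_duplication(
    anc, c(1000, 2000),
    duplication_spec(n_complete = 2, partial_length = 150, per_copy_divergence = 0.03, seed = 6)
  )
  tags <- suppressWarnings(select_tags(region, spacing = 600, tag_length = 120))
  hap <- make_donor_haplotypes(
    region, list(variant_spec(delete_units = 1), variant_spec()),
    seed = 2
  )$H1
  for (k in seq_len(nrow(tags))) {
    w <- substr(region$seq, tags$start[k] + 1, tags$end[k])
    expect_lte(count_occurrences(w, hap), 1)
  }
})
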