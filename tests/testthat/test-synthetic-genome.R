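test_that("ancestral region construction places disjoint gene segments deterministically", {
  tpl <- fixed_templates(2, 450)
  r1 <- build_ancestral_region(3000, tpl, seed = 1)
  r2 <- build_ancestral_region(3000, tpl, seed = 1)
  r3 <- build_ancestral_region(3000, tpl, seed = 2)

  expect_equal(region_length(r1), 3000)
  genes <- region_features(r1, "gene_segment")
  expect_equal(nrow(genes), 2)
  genes <- genes[order(genes$start), ]
  expect_true(genes$end[1] <= genes$start[2])

  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$features, r2$features)
  expect_false(identical(r1$seq, r3$seq))

  expect_error(
    build_ancestral_region(500, tpl, seed = 1),
    class = "ighv_sizing_error"
  )
})

test_that("planting a zero-divergence duplication yields identical tandem copies", {
  withr::with_seed(11, {
    anc <- annotated_region("r", random_seq(1500))
  })
  out <- plant_duplication(
    anc, c(400, 900),
    duplication_spec(n_complete = 2, partial_length = 100, per_copy_divergence = 0, seed = 3)
  )
  units <- region_features(out, "repeat_unit")
  units <- units[order(units$start), ]
  expect_equal(nrow(units), 3)
  expect_equal(units$end - units$start, c(500, 500, 100))
  c1 <- substr(out$seq, 401, 900)
  c2 <- substr(out$seq, 901, 1400)
  c3 <- substr(out$seq, 1401, 1500)
  expect_identical(c1, c2)
  expect_identical(c3, substr(c1, 1, 100))
  expect_equal(region_length(out), 1500 + 500 + 100)
})

test_that("planted copy divergence matches the per-copy mutation rate", {
  withr::with_seed(12, {
    anc <- annotated_region("r", random_seq(2800))
  })
  out <- plant_duplication(
    anc, c(400, 2400),
    duplication_spec(n_complete = 2, partial_length = 200, per_copy_divergence = 0.05, seed = 8)
  )
  c1 <- substr(out$seq, 401, 2400)
  c2 <- substr(out$seq, 2401, 4400)
  mism <- sum(utf8ToInt(c1) != utf8ToInt(c2))
  identity <- 1 - mism / 2000
  # two copies each 5% mutated: expected pairwise identity ~0.903
  expect_gt(identity, 0.88)
  expect_lt(identity, 0.93)
})

test_that("the two-complete-plus-partial topology scales to the published proportions", {
  unit <- 2470 # 1/10 scale of the 24,696 bp unit
  partial <- round(961 / 24696 * unit)
  withr::with_seed(13, {
    anc <- annotated_region("r", random_seq(unit + 800))
  })
  out <- plant_duplication(
    anc, c(400, 400 + unit),
    duplication_spec(n_complete = 2, partial_length = partial, per_copy_divergence = 0.022, seed = 5)
  )
  units <- region_features(out, "repeat_unit")
  units <- units[order(units$start), ]
  expect_equal(nrow(units), 3)
  expect_equal(units$end[1:2] - units$start[1:2], c(unit, unit))
  expect_equal(units$end[3] - units$start[3], partial)
})

test_that("mutate_seq reports exactly the substitutions it makes", {
  s <- strrep("ACGT", 50)
  expect_identical(mutate_seq(s, 0, seed = 1)$seq, s)
  expect_equal(mutate_seq(s, 0, seed = 1)$n_substitutions, 0L)
  for (seed in 1:20) {
    m <- mutate_seq(s, 0.1, seed = seed)
    expect_equal(sum(utf8ToInt(m$seq) != utf8ToInt(s)), m$n_substitutions)
    expect_equal(length(m$positions), m$n_substitutions)
  }
  expect_error(mutate_seq(s, 1), class = "ighv_parameter_error")
  expect_error(mutate_seq(s, -0.1), class = "ighv_parameter_error")
})

test_that("substitution counts follow the binomial expectation", {
  s <- withr::with_seed(14, random_seq(10000))
  counts <- vapply(1:200, function(seed) {
    mutate_seq(s, 0.05, seed = seed)$n_substitutions
  }, integer(1))
  # mean of 200 replicates within 3 standard errors of Binomial(10000, 0.05)
  se <- sqrt(10000 * 0.05 * 0.95) / sqrt(200)
  expect_lt(abs(mean(counts) - 500), 3 * se)
})

test_that("donor haplotype edits delete copies and shift coordinates consistently", {
  withr::with_seed(15, {
    anc <- annotated_region("r", random_seq(2000))
  })
  region <- plant_duplication(
    anc, c(500, 1000),
    duplication_spec(n_complete = 2, partial_length = 100, per_copy_divergence = 0.02, seed = 2)
  )

  same <- make_donor_haplotypes(region, list(variant_spec(), variant_spec()), seed = 1)
  expect_identical(same$H1$seq, region$seq)
  expect_identical(same$H2$seq, region$seq)

  del <- make_donor_haplotypes(
    region, list(variant_spec(delete_units = 1), variant_spec()),
    seed = 1
  )
  expect_equal(region_length(del$H1), region_length(region) - 500)
  expect_equal(
    nrow(region_features(del$H1, "repeat_unit")),
    nrow(region_features(region, "repeat_unit")) - 1
  )
  validate_region(del$H1)

  expect_error(
    make_donor_haplotypes(region, list(variant_spec(delete_units = 9), variant_spec())),
    class = "ighv_spec_error"
  )
})

test_that("extra haplotype divergence creates tag-sized mismatch windows inside the repeat", {
  withr::with_seed(16, {
    anc <- annotated_region("r", random_seq(2000))
  })
  region <- plant_duplication(
    anc, c(500, 1000),
    duplication_spec(n_complete = 2, partial_length = 100, per_copy_divergence = 0, seed = 2)
  )
  hap <- make_donor_haplotypes(
    region, list(variant_spec(extra_divergence = 0.02), variant_spec()),
    seed = 4
  )$H1
  units <- region_features(region, "repeat_unit")
  span <- seq_window(region$seq, units$start[1], units$end[1])
  span_h <- seq_window(hap$seq, units$start[1], units$end[1])
  mism <- sum(utf8ToInt(span) != utf8ToInt(span_h))
  expect_gt(mism, 0)
  expect_lt(mism / nchar(span), 0.05)
  # untouched flank is identical
  expect_identical(substr(hap$seq, 1, 500), substr(region$seq, 1, 500))
})

test_that("feature bookkeeping survives random duplication and deletion edits", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      tpl <- lapply(1:2, function(i) {
        gene_template(paste0("g", i), random_seq(120), rbind(c(0, 30), c(60, 120)))
      })
      anc <- build_ancestral_region(1500, tpl, seed = NULL, min_spacer = 50)
      s <- sample(0:400, 1)
      L <- sample(200:400, 1)
      region <- suppressWarnings(plant_duplication(
        anc, c(s, s + L),
        duplication_spec(
          n_complete = 2, partial_length = sample(30:100, 1),
          per_copy_divergence = 0.02, seed = NULL
        )
      ))
      hap <- suppressWarnings(make_donor_haplotypes(
        region,
        list(variant_spec(delete_units = 1, extra_divergence = 0.01), variant_spec()),
        seed = NULL
      ))
      # validate_region() asserts interval bounds and exon/gene nesting
      expect_no_error(validate_region(region))
      expect_no_error(validate_region(hap$H1))
      expect_no_error(validate_region(hap$H2))
    })
  }
})
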