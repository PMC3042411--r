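gm_from_matrix <- function(mat, tags) {
  # mat: sperm x tags of TRUE (detected) / FALSE
  out <- tibble::tibble(
    sperm_id = rep(sprintf("S%02d", seq_len(nrow(mat))), each = ncol(mat)),
    tag = rep(tags, nrow(mat)),
    call = ifelse(as.vector(t(mat)), "detected", "undetected")
  )
  structure(out, class = c("sperm_genotypes", class(out)), tags = tags, donor = "T")
}

test_that("a clean four-sperm panel phases exactly", {
  tags <- c("A", "B", "C", "D")
  mat <- rbind(
    c(TRUE, TRUE, TRUE, TRUE),
    c(TRUE, FALSE, FALSE, TRUE),
    c(TRUE, TRUE, TRUE, TRUE),
    c(TRUE, FALSE, FALSE, TRUE)
  )
  ph <- phase_sperm(gm_from_matrix(mat, tags), min_support = 2, consensus_frac = 0.7)
  expect_setequal(status_sets(ph), c("++++", "+udud+"))
  # assignments put identical rows together
  a <- ph$assignments$haplotype
  expect_equal(a[1], a[3])
  expect_equal(a[2], a[4])
  expect_false(a[1] == a[2])
})

test_that("noise-free phasing recovers the planted partition for all seeds", {
  truth <- truth_pattern_pair()
  for (seed in 1:20) {
    gm <- simulate_sperm_panel(
      NULL, NULL,
      n_sperm = 40, noise = noise_model(0, 0, seed = seed), truth = truth
    )
    ph <- phase_sperm(gm)
    expect_identical(status_sets(ph), truth_status_sets(truth))
    # planted partition recovered exactly (up to label swap)
    truth_assign <- attr(gm, "truth_assignment")$haplotype
    est <- ph$assignments$haplotype
    expect_true(all(est == truth_assign) || all(est != truth_assign))
  }
})

test_that("a tag undetected in every sperm is called ud on both haplotypes", {
  truth <- truth_pattern_pair()
  gm <- simulate_sperm_panel(
    NULL, NULL,
    n_sperm = 50, noise = noise_model(0, 0, seed = 9), truth = truth
  )
  ph <- phase_sperm(gm)
  both <- ph$haplotypes[ph$haplotypes$tag == "T04", ]
  expect_equal(both$status, c("ud", "ud"))
})

test_that("homozygous panels report one common pattern instead of a noise split", {
  truth <- tibble::tibble(
    haplotype = rep(c("H1", "H2"), each = 8),
    tag = rep(sprintf("T%d", 1:8), 2),
    detectable = rep(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE), 2)
  )
  for (seed in 1:10) {
    gm <- simulate_sperm_panel(
      NULL, NULL,
      n_sperm = 50, noise = noise_model(0.05, 0.01, seed = seed), truth = truth
    )
    ph <- phase_sperm(gm)
    expect_false(ph$separated)
    expect_identical(status_sets(ph)[1], status_sets(ph)[2])
  }
})

test_that("phasing refuses panels smaller than twice the support threshold", {
  tags <- c("A", "B")
  mat <- matrix(TRUE, nrow = 6, ncol = 2)
  expect_error(
    phase_sperm(gm_from_matrix(mat, tags), min_support = 5),
    class = "ighv_insufficient_data_error"
  )
})

test_that("tag classification distinguishes polymorphic from universally undetectable", {
  calls <- dplyr::bind_rows(
    tibble::tibble(donor = "D1", haplotype = "H1", tag = c("A", "B", "C"), status = c("+", "ud", "+")),
    tibble::tibble(donor = "D1", haplotype = "H2", tag = c("A", "B", "C"), status = c("+", "ud", "-")),
    tibble::tibble(donor = "D2", haplotype = "H1", tag = c("A", "B", "C"), status = c("+", "ud", "+"))
  )
  cl <- classify_tags(calls, tag_order = c("A", "B", "C"))
  expect_equal(cl$class, c("non_polymorphic_detected", "undetectable_in_all", "polymorphic"))

  all_plus <- tibble::tibble(
    donor = rep(c("D1", "D1"), each = 2),
    haplotype = rep(c("H1", "H2"), each = 2),
    tag = rep(c("A", "B"), 2), status = "+"
  )
  expect_true(all(classify_tags(all_plus)$class == "non_polymorphic_detected"))

  single <- tibble::tibble(donor = "D1", haplotype = "H1", tag = "A", status = "+")
  expect_error(classify_tags(single), class = "ighv_insufficient_data_error")
})

test_that("undetectable runs are maximal and respect tag order", {
  tags <- sprintf("T%d", 1:8)
  calls <- tibble::tibble(
    tag = tags,
    status = c("+", "ud", "-", "+", "+", "ud", "ud", "ud")
  )
  runs <- find_undetectable_runs(calls, tag_order = tags)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$start_tag, c("T2", "T6"))
  expect_equal(runs$end_tag, c("T3", "T8"))
  expect_equal(runs$length, c(2L, 3L))

  clean <- tibble::tibble(tag = tags, status = rep("+", 8))
  expect_equal(nrow(find_undetectable_runs(clean, tag_order = tags)), 0)
})

test_that("polymorphic region delimitation finds the span and its detected flanks", {
  classes <- tibble::tibble(
    tag = sprintf("T%d", 1:7),
    class = c(
      "non_polymorphic_detected", "undetectable_in_all", "polymorphic",
      "non_polymorphic_detected", "polymorphic", "non_polymorphic_detected",
      "non_polymorphic_detected"
    )
  )
  d <- delimit_polymorphic_region(classes)
  expect_equal(d$first_tag, "T3")
  expect_equal(d$last_tag, "T5")
  expect_equal(d$flank_left, "T1")
  expect_equal(d$flank_right, "T6")

  none <- tibble::tibble(tag = c("A", "B"), class = rep("non_polymorphic_detected", 2))
  expect_equal(nrow(delimit_polymorphic_region(none)), 0)

  one <- tibble::tibble(
    tag = c("A", "B", "C"),
    class = c("non_polymorphic_detected", "polymorphic", "non_polymorphic_detected")
  )
  d1 <- delimit_polymorphic_region(one)
  expect_equal(d1$first_tag, "B")
  expect_equal(d1$last_tag, "B")
})

test_that("tidy and glance summarise a phasing fit", {
  truth <- truth_pattern_pair()
  gm <- simulate_sperm_panel(
    NULL, NULL,
    n_sperm = 50, noise = noise_model(0.05, 0.01, seed = 3), truth = truth
  )
  ph <- phase_sperm(gm)
  td <- tidy(ph)
  expect_true(all(c("donor", "haplotype", "tag", "status", "n_detected", "n_assigned") %in% names(td)))
  expect_equal(nrow(td), 2 * 17)
  g <- glance(ph)
  expect_equal(g$n_sperm, 50L)
  expect_equal(g$n_tags, 17L)
  expect_true(g$separated)
})
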