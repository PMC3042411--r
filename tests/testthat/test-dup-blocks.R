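test_that("self-comparison of a repeat-free sequence gives only the main diagonal", {
  a <- "ACGGTTCAACGT" # 12 bp, no repeated 9-mers
  m <- dot_matches(a, a, dot_params(window = 9))
  expect_equal(nrow(m), 4)
  expect_true(all(m$i == m$j))
})

test_that("a period-4 sequence yields the hand-derived and oracle match sets", {
  a <- "ACGTACGTACGTACGT"
  m <- dot_matches(a, a, dot_params(window = 9))
  expect_equal(nrow(m), 16)
  diag <- m$j - m$i
  expect_equal(sum(diag == 0), 8)
  expect_equal(sum(diag == 4), 4)
  expect_equal(sum(diag == -4), 4)
  oracle <- oracle_dot_matches(a, a, 9, 0)
  expect_equal(as.data.frame(m[, c("i", "j")]), oracle, ignore_attr = TRUE)
})

test_that("self-comparison match sets are symmetric", {
  withr::with_seed(40, {
    a <- paste0(random_seq(150), substr(random_seq(150), 1, 60))
  })
  m <- dot_matches(a, a, dot_params(window = 8, max_mismatch = 1))
  key <- paste(m$i, m$j)
  swapped <- paste(m$j, m$i)
  expect_setequal(key, swapped)
})

test_that("sequences shorter than the window give no matches", {
  m <- dot_matches("ACGT", "ACGTACGT", dot_params(window = 9))
  expect_equal(nrow(m), 0)
})

test_that("hash-seeded matching equals the brute-force oracle on random pairs", {
  withr::with_seed(41, {
    for (rep in 1:50) {
      na <- sample(80:300, 1)
      nb <- sample(80:300, 1)
      w <- sample(6:12, 1)
      mm <- sample(0:2, 1)
      if (mm >= w) mm <- 0
      a <- random_seq(na)
      b <- if (runif(1) < 0.3) paste0(substr(a, 1, na %/% 2), random_seq(nb %/% 2)) else random_seq(nb)
      m <- dot_matches(a, b, dot_params(window = w, max_mismatch = mm))
      oracle <- oracle_dot_matches(a, b, w, mm)
      expect_equal(as.data.frame(m[, c("i", "j")]), oracle, ignore_attr = TRUE)
    }
  })
})

test_that("hash-seeded matching equals the oracle on kilobase-scale inputs", {
  withr::with_seed(42, {
    base <- random_seq(1800)
    b <- paste0(substr(base, 501, 1400), random_seq(600))
    for (mm in 0:1) {
      m <- dot_matches(base, b, dot_params(window = 9, max_mismatch = mm))
      oracle <- oracle_dot_matches(base, b, 9, mm)
      expect_equal(as.data.frame(m[, c("i", "j")]), oracle, ignore_attr = TRUE)
    }
  })
})

test_that("diagonal chaining follows the hand-worked example and the gap rule", {
  matches <- tibble::tibble(i = c(0L, 1L, 2L, 3L), j = c(4L, 5L, 6L, 7L))
  runs <- diagonal_runs(matches, min_run = 1, max_gap = 1, window = 9)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$a_start, 0)
  expect_equal(runs$length, 12)
  expect_equal(runs$diagonal, 4)

  expect_equal(nrow(diagonal_runs(tibble::tibble(i = integer(), j = integer()),
    min_run = 1, max_gap = 1, window = 9
  )), 0)

  # two clusters on one diagonal separated by more than max_gap
  far <- tibble::tibble(i = c(0L, 1L, 50L, 51L), j = c(10L, 11L, 60L, 61L))
  runs2 <- diagonal_runs(far, min_run = 1, max_gap = 10, window = 9)
  expect_equal(nrow(runs2), 2)
})

test_that("self-comparison always yields the full main diagonal as one run", {
  withr::with_seed(43, {
    a <- random_seq(400)
  })
  m <- dot_matches(a, a, dot_params(window = 9))
  runs <- diagonal_runs(m[m$i == m$j, ], min_run = 9, max_gap = 5, window = 9)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$a_start, 0)
  expect_equal(runs$length, 400)
})

test_that("planted tandem duplications are recovered with correct copy structure", {
  fx <- planted_dup_region(unit = 500, partial = 120, div = 0.0125, seed = 7)
  blocks <- find_repeat_units(
    fx$region, dot_params(window = 9, max_mismatch = 1),
    min_unit = 200
  )
  expect_equal(nrow(blocks), 3)
  expect_equal(blocks$complete, c(TRUE, TRUE, FALSE))
  expect_equal(attr(blocks, "unit_length"), 500)
  expect_true(all(abs(blocks$start - fx$truth_starts) <= 9))
  expect_lte(abs(blocks$end[3] - fx$truth_end), 9)
})

test_that("random sequence contains no repeat units", {
  withr::with_seed(44, {
    a <- random_seq(5000)
  })
  blocks <- find_repeat_units(a, dot_params(window = 9), min_unit = 200)
  expect_equal(nrow(blocks), 0)
})

test_that("a haplotype missing one copy reports one fewer complete copy", {
  fx <- planted_dup_region(unit = 500, partial = 120, div = 0.0125, seed = 8)
  hap <- make_donor_haplotypes(
    fx$region, list(variant_spec(delete_units = 1), variant_spec()),
    seed = 3
  )$H1
  p <- dot_params(window = 9, max_mismatch = 1)
  bA <- find_repeat_units(fx$region, p, min_unit = 200)
  bB <- find_repeat_units(hap, p, min_unit = 200)
  expect_equal(sum(bA$complete), 2)
  expect_equal(sum(bB$complete), 1)
})

test_that("conserved-block mapping localises an internal deletion breakpoint", {
  withr::with_seed(45, {
    a <- random_seq(2000)
  })
  b <- paste0(substr(a, 1, 1000), substr(a, 1301, 2000)) # 300 bp deletion
  p <- dot_params(window = 9)
  runs <- map_conserved_blocks(a, b, p, min_run = 200, max_gap = 30)
  expect_equal(nrow(runs), 2)
  expect_equal(abs(diff(runs$diagonal)), 300)

  # identical sequences: one run covering everything
  full <- map_conserved_blocks(a, a, p, min_run = 200, max_gap = 30)
  expect_equal(nrow(full), 1)
  expect_equal(full$length, 2000)

  # reverse complement is invisible on the forward strand
  rc <- map_conserved_blocks(a, revcomp(a), p, min_run = 200, max_gap = 30)
  expect_equal(nrow(rc), 0)
})
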