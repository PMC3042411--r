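DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a local, explicit random seed
#'
#' Global RNG state is never consumed when `seed` is given; `NULL` means
#' "inherit the current RNG stream" so nested calls can share one seed.
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

#' Round half away from zero at a fixed number of decimals
#'
#' Printed percentages and per-1,200-bp figures use commercial (half-up)
#' rounding, not banker's rounding; the epsilon guards against binary
#' representation of values like 2.5 stored as 2.4999...
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
#' @examples
#' round_half_up(6.6210, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Uniform random DNA sequence (consumes the current RNG stream)
#' @noRd
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming_str <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Reverse complement of a DNA string
#' @param x a character scalar over A/C/G/T
#' @return the reverse-complemented character scalar
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a 0-based half-open window from a sequence string
#' @noRd
seq_window <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

#' Derive a reproducible stage seed from a master seed and a stage name
#'
#' Stage names are hashed so adding a stage never shifts the randomness of
#' the others. Kept below 2^31 - 1.
#' @noRd
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(master_seed) %% 1000003L) * 1009L + (h %% 99991L)
}
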