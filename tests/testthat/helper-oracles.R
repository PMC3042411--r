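# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (hash seeding, Biostrings search, chaining) so that a bug
# cannot cancel out of both sides of a comparison.

# All (i, j) window pairs within mm substitutions, by per-diagonal scan with
# running sums of position-wise equality.
oracle_dot_matches <- function(a, b, w, mm) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  na <- length(av)
  nb <- length(bv)
  out_i <- integer(0)
  out_j <- integer(0)
  for (d in (-(na - w)):(nb - w)) {
    i0 <- max(0L, -d)
    j0 <- i0 + d
    len <- min(na - i0, nb - j0)
    if (len < w) next
    eq <- av[(i0 + 1):(i0 + len)] == bv[(j0 + 1):(j0 + len)]
    cs <- cumsum(eq)
    n_start <- len - w + 1L
    matched <- (cs[w:len] - c(0, cs[seq_len(n_start - 1L)])) >= (w - mm)
    hits <- which(matched) - 1L
    out_i <- c(out_i, i0 + hits)
    out_j <- c(out_j, j0 + hits)
  }
  ord <- order(out_i, out_j)
  data.frame(i = out_i[ord], j = out_j[ord])
}

# Sliding-window occurrence count with mismatches.
oracle_count_occurrences <- function(subseq, seq, mm = 0) {
  k <- nchar(subseq)
  n <- nchar(seq)
  if (n < k) {
    return(0L)
  }
  qv <- utf8ToInt(subseq)
  count <- 0L
  for (p in 0:(n - k)) {
    if (sum(utf8ToInt(substr(seq, p + 1, p + k)) != qv) <= mm) count <- count + 1L
  }
  count
}

# Three-state affine-gap global alignment score; a gap of length k costs
# |gap_open| + k * |gap_extend|.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -2, gap_extend = -1) {
  go <- abs(gap_open)
  ge <- abs(gap_extend)
  n <- nchar(a)
  m <- nchar(b)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(neg, n + 1, m + 1) # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + (i - 1) * ge)
  for (j in 2:(m + 1)) Y[1, j] <- -(go + (j - 1) * ge)
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i > 1 && j > 1) {
        s <- if (av[i - 1] == bv[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      }
      if (i > 1) {
        X[i, j] <- max(X[i, j], M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      }
      if (j > 1) {
        Y[i, j] <- max(Y[i, j], M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      }
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Stop-reachable sense codons enumerated from the stop side: all single-base
# neighbours of the stop codons, intersected with the sense codons.
oracle_stop_reachable <- function(code = Biostrings::GENETIC_CODE) {
  stops <- names(code)[code == "*"]
  sense <- names(code)[code != "*"]
  nbrs <- character(0)
  for (s in stops) {
    for (pos in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b != substr(s, pos, pos)) {
          x <- s
          substr(x, pos, pos) <- b
          nbrs <- c(nbrs, x)
        }
      }
    }
  }
  sort(intersect(unique(nbrs), sense))
}

# ORF scan through Biostrings translation (different route from the
# package's codon-table lookup).
oracle_in_orf <- function(exons, frame = 0) {
  cds <- substr(paste(exons, collapse = ""), frame + 1, nchar(paste(exons, collapse = "")))
  cds <- substr(cds, 1, 3 * (nchar(cds) %/% 3))
  if (nchar(cds) < 3) {
    return(TRUE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  internal <- substr(aa, 1, nchar(aa) - 1)
  !grepl("\\*", internal)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
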