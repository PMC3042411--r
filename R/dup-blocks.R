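#' Dot-matrix comparison parameters
#'
#' Window size 9 with exact matching mirrors the classic dot-matrix tool
#' used for self-comparison of this locus; a small mismatch tolerance is
#' exposed because diverged duplicate copies thin out exact 9-mer diagonals.
#'
#' @param window window size in bp (`>= 4`).
#' @param max_mismatch substitutions tolerated per window (`< window`).
#' @param strand `"forward_only"` (direct repeats; the default) or `"both"`.
#' @return a `dot_params` list.
#' @export
dot_params <- function(window = 9, max_mismatch = 0,
                       strand = c("forward_only", "both")) {
  strand <- match.arg(strand)
  if (window < 4) abort("window must be >= 4", class = "ighv_parameter_error")
  if (max_mismatch >= window) {
    abort("max_mismatch must be smaller than window", class = "ighv_parameter_error")
  }
  structure(
    list(window = as.integer(window), max_mismatch = as.integer(max_mismatch), strand = strand),
    class = "dot_params"
  )
}

#' Exact window-match pairs between two sequences
#' @noRd
exact_window_matches <- function(a, b, w) {
  na <- nchar(a) - w + 1L
  nb <- nchar(b) - w + 1L
  if (na < 1L || nb < 1L) {
    return(tibble(i = integer(), j = integer()))
  }
  wa <- substring(a, 1:na, w:(na + w - 1L))
  wb <- substring(b, 1:nb, w:(nb + w - 1L))
  idx <- split(seq_len(nb), wb)
  hits <- idx[wa]
  lens <- lengths(hits)
  tibble(
    i = rep.int(seq_len(na), lens) - 1L,
    j = unlist(hits, use.names = FALSE) - 1L
  )
}

#' Window matches between two sequences (dot-matrix plot points)
#'
#' Reports every pair of 0-based window starts `(i, j)` whose windows
#' `a[i, i+w)` and `b[j, j+w)` differ at no more than `max_mismatch`
#' positions. Matching is hash-seeded rather than all-vs-all: exact windows
#' are found through a window index; tolerant matching seeds candidate
#' pairs from exact sub-segments (any window pair within the tolerance must
#' share one of `max_mismatch + 1` exact segments) and verifies each
#' candidate, which reproduces the naive definition exactly.
#'
#' @param a,b nucleotide sequences (strings or [annotated_region()]s).
#' @param p a [dot_params()] list.
#' @return a tibble `i`, `j` (plus `strand` when both strands are scanned),
#'   sorted, with `window` attached as an attribute.
#' @export
dot_matches <- function(a, b, p = dot_params()) {
  a <- as_seq(a)
  b <- as_seq(b)
  w <- p$window
  out <- dot_matches_one(a, b, w, p$max_mismatch)
  if (p$strand == "both") {
    rc <- dot_matches_one(a, revcomp(b), w, p$max_mismatch)
    nb <- nchar(b) - w + 1L
    rc$j <- nb - 1L - rc$j # window start back on forward coordinates of b
    out <- bind_rows(mutate(out, strand = "+"), mutate(rc, strand = "-"))
  }
  out <- arrange(out, .data$i, .data$j)
  attr(out, "window") <- w
  out
}

#' @noRd
dot_matches_one <- function(a, b, w, mm) {
  if (mm == 0L) {
    return(exact_window_matches(a, b, w))
  }
  na <- nchar(a) - w + 1L
  nb <- nchar(b) - w + 1L
  if (na < 1L || nb < 1L) {
    return(tibble(i = integer(), j = integer()))
  }
  # pigeonhole seeding: split the window into mm + 1 segments
  n_seg <- mm + 1L
  seg_bounds <- floor(seq(0L, w, length.out = n_seg + 1L))
  cand_i <- integer(0)
  cand_j <- integer(0)
  for (s in seq_len(n_seg)) {
    off <- seg_bounds[s]
    slen <- seg_bounds[s + 1L] - off
    seg <- exact_window_matches(
      substr(a, 1L, nchar(a)), substr(b, 1L, nchar(b)), slen
    )
    ii <- seg$i - off
    jj <- seg$j - off
    keep <- ii >= 0L & jj >= 0L & ii < na & jj < nb
    cand_i <- c(cand_i, ii[keep])
    cand_j <- c(cand_j, jj[keep])
  }
  if (!base::length(cand_i)) {
    return(tibble(i = integer(), j = integer()))
  }
  key <- cand_i * (nb + 1) + cand_j
  keep <- !duplicated(key)
  cand_i <- cand_i[keep]
  cand_j <- cand_j[keep]
  wa <- substring(a, cand_i + 1L, cand_i + w)
  wb <- substring(b, cand_j + 1L, cand_j + w)
  mmv <- mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), wa, wb,
    USE.NAMES = FALSE
  )
  ok <- mmv <= mm
  tibble(i = cand_i[ok], j = cand_j[ok])
}

#' Chain dot-matrix matches into diagonal runs
#'
#' Matches on one diagonal (`j - i` constant) whose consecutive window
#' starts differ by at most `max_gap` are chained into a run; a run spans
#' from its first window start to its last window end and runs shorter than
#' `min_run` are discarded.
#'
#' @param matches a tibble from [dot_matches()].
#' @param min_run minimum run span in bp.
#' @param max_gap maximum start-to-start gap chained over, bp. Permissive
#'   gaps let runs bridge the window dropouts caused by copy divergence.
#' @param window window size; taken from the `matches` attribute if absent.
#' @return a tibble `a_start`, `a_end`, `b_start`, `b_end`, `diagonal`,
#'   `length`, `n_matches`, sorted by position.
#' @export
diagonal_runs <- function(matches, min_run = 27, max_gap = 50, window = NULL) {
  w <- window %||% attr(matches, "window")
  if (is.null(w)) abort("window size not supplied", class = "ighv_parameter_error")
  if (nrow(matches) == 0) {
    return(tibble(
      a_start = integer(), a_end = integer(), b_start = integer(),
      b_end = integer(), diagonal = integer(), length = integer(),
      n_matches = integer()
    ))
  }
  m <- matches |>
    mutate(diagonal = .data$j - .data$i) |>
    arrange(.data$diagonal, .data$i) |>
    group_by(.data$diagonal) |>
    mutate(run = cumsum(c(0L, diff(.data$i)) > max_gap)) |>
    group_by(.data$diagonal, .data$run) |>
    summarise(
      a_start = min(.data$i), a_end = max(.data$i) + w,
      b_start = min(.data$j), b_end = max(.data$j) + w,
      n_matches = dplyr::n(), .groups = "drop"
    ) |>
    mutate(length = .data$a_end - .data$a_start) |>
    filter(.data$length >= min_run) |>
    arrange(.data$a_start, .data$diagonal) |>
    dplyr::select(
      "a_start", "a_end", "b_start", "b_end", "diagonal", "length", "n_matches"
    )
  m
}

#' Infer tandem repeat copies from dot-matrix self-comparison
#'
#' Off-diagonal runs of the self-comparison reveal the duplication: the
#' smallest diagonal offset carrying a substantial run is the repeat unit
#' length, and the union of run spans on that diagonal delimits the
#' repeated region. Copies are laid out from the region start at unit
#' steps; a copy spanning at least 90% of a unit is flagged complete,
#' shorter trailing overlap is an incomplete (truncated) copy.
#'
#' `min_unit` filters the candidate unit length (the diagonal); run spans
#' only need to reach `min_run`, so a single remaining complete copy plus a
#' short truncated copy is still recognised from their short mutual run.
#'
#' @param region_seq sequence string or [annotated_region()].
#' @param p a [dot_params()] list.
#' @param min_unit minimum unit length considered, bp.
#' @param min_run minimum chained run span kept, bp.
#' @param max_gap chaining gap, bp.
#' @param min_density minimum window matches per bp of run span for a run
#'   to count as duplication evidence. Genuine copies at the divergence
#'   levels seen here keep most windows matching (density well above 0.5);
#'   chance chains of isolated window hits sit far below the default 0.3.
#' @return a `repeat_blocks` tibble `copy`, `start`, `end`, `length`,
#'   `complete`, with attribute `unit_length`; zero rows when no repeat is
#'   found.
#' @export
find_repeat_units <- function(region_seq, p = dot_params(), min_unit = 200,
                              min_run = 3 * p$window, max_gap = 50,
                              min_density = 0.3) {
  seq <- as_seq(region_seq)
  matches <- dot_matches(seq, seq, p)
  matches <- matches[matches$j > matches$i, ]
  runs <- diagonal_runs(matches, min_run = min_run, max_gap = max_gap, window = p$window)
  empty <- tibble(
    copy = integer(), start = integer(), end = integer(),
    length = integer(), complete = logical()
  )
  runs <- runs[runs$diagonal >= min_unit & runs$n_matches >= min_density * runs$length, ]
  if (nrow(runs) == 0) {
    attr(empty, "unit_length") <- NA_integer_
    return(structure(empty, class = c("repeat_blocks", class(empty))))
  }
  unit <- min(runs$diagonal)
  # allow window-scale jitter around the unit diagonal
  on_unit <- runs[abs(runs$diagonal - unit) <= p$window, ]
  rep_start <- min(on_unit$a_start)
  rep_end <- max(on_unit$a_end) + unit
  starts <- seq(rep_start, rep_end - 1L, by = unit)
  out <- tibble(
    copy = seq_along(starts),
    start = as.integer(starts),
    end = as.integer(pmin(starts + unit, rep_end))
  ) |>
    mutate(length = .data$end - .data$start, complete = .data$length >= 0.9 * unit)
  attr(out, "unit_length") <- as.integer(unit)
  structure(out, class = c("repeat_blocks", class(out)))
}

#' Map conserved blocks between two haplotype sequences
#'
#' Cross-comparison dot matches chained into diagonal runs, reported in
#' both coordinate systems. Adjacent runs on different diagonals flank the
#' breakpoints where insertion/deletion or shuffling changed the register.
#'
#' @param a,b sequences (strings or [annotated_region()]s).
#' @param p a [dot_params()] list.
#' @param min_run minimum block span, bp.
#' @param max_gap chaining gap, bp.
#' @return a tibble of runs as in [diagonal_runs()], ordered along `a`,
#'   with a `breakpoints` attribute (positions in `a` between adjacent runs
#'   whose diagonals differ).
#' @export
map_conserved_blocks <- function(a, b, p = dot_params(), min_run = 100, max_gap = 50) {
  runs <- diagonal_runs(
    dot_matches(a, b, p),
    min_run = min_run, max_gap = max_gap, window = p$window
  )
  runs <- arrange(runs, .data$a_start)
  if (nrow(runs) > 1) {
    shift <- runs$diagonal[-1] != runs$diagonal[-nrow(runs)]
    attr(runs, "breakpoints") <- runs$a_end[-nrow(runs)][shift]
  } else {
    attr(runs, "breakpoints") <- integer(0)
  }
  runs
}
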