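#' Annotated genomic region
#'
#' A light container pairing one nucleotide sequence with a feature table.
#' All coordinates are 0-based half-open (BED convention); GFF-style 1-based
#' closed coordinates appear only at export time.
#'
#' @param name region identifier.
#' @param seq nucleotide sequence (character scalar over A/C/G/T).
#' @param features a tibble with columns `kind` (one of `gene_segment`,
#'   `exon`, `repeat_unit`, `tag`), `start`, `end` (0-based half-open),
#'   `name`, `strand` (`+`/`-`), `functional` (logical, gene segments only)
#'   and `parent` (exons reference their gene segment).
#' @return an object of class `annotated_region`.
#' @export
#' @examples
#' r <- annotated_region("toy", "ACGTACGT")
#' region_length(r)
annotated_region <- function(name, seq, features = empty_features()) {
  x <- structure(
    list(name = name, seq = toupper(seq), features = as_tibble(features)),
    class = "annotated_region"
  )
  validate_region(x)
  x
}

FEATURE_KINDS <- c("gene_segment", "exon", "repeat_unit", "tag")

#' Empty feature table with the canonical columns
#' @return a zero-row feature tibble
#' @export
empty_features <- function() {
  tibble(
    kind = character(), start = integer(), end = integer(),
    name = character(), strand = character(),
    functional = logical(), parent = character()
  )
}

#' Validate an annotated region's invariants
#'
#' Checks the alphabet, feature intervals, kinds and exon/gene nesting;
#' aborts with a classed condition on violation.
#' @param x an `annotated_region`.
#' @return `x`, invisibly.
#' @export
validate_region <- function(x) {
  if (!nzchar(x$seq)) {
    abort("region sequence must be non-empty", class = "ighv_region_error")
  }
  if (grepl("[^ACGT]", x$seq)) {
    abort("region sequence contains characters outside A/C/G/T",
      class = "ighv_region_error"
    )
  }
  f <- x$features
  if (nrow(f)) {
    if (!all(f$kind %in% FEATURE_KINDS)) {
      abort("unknown feature kind", class = "ighv_region_error")
    }
    bad <- f$start < 0L | f$end > nchar(x$seq) | f$start >= f$end
    if (any(bad)) {
      abort(
        paste0("feature interval out of bounds: ", f$name[bad][1]),
        class = "ighv_region_error"
      )
    }
    ex <- f[f$kind == "exon", ]
    if (nrow(ex)) {
      genes <- f[f$kind == "gene_segment", ]
      ok <- map_lgl(seq_len(nrow(ex)), function(i) {
        g <- genes[genes$name == ex$parent[i], ]
        nrow(g) == 1 && ex$start[i] >= g$start && ex$end[i] <= g$end
      })
      if (!all(ok)) {
        abort("exon not nested in its parent gene segment",
          class = "ighv_region_error"
        )
      }
    }
  }
  invisible(x)
}

#' Length of a region's sequence in bp
#' @param x an `annotated_region`.
#' @return integer length
#' @export
region_length <- function(x) nchar(x$seq)

#' Feature table of a region, optionally filtered by kind
#' @param x an `annotated_region`.
#' @param kind optional feature kind to filter on.
#' @return a feature tibble
#' @export
region_features <- function(x, kind = NULL) {
  f <- x$features
  if (!is.null(kind)) f <- f[f$kind %in% kind, ]
  f
}

#' @export
print.annotated_region <- function(x, ...) {
  cat(sprintf(
    "<annotated_region> %s: %s bp, %d features\n",
    x$name, format(nchar(x$seq), big.mark = ","), nrow(x$features)
  ))
  if (nrow(x$features)) {
    print(dplyr::count(x$features, .data$kind))
  }
  invisible(x)
}

#' Shift features at or beyond an offset by a signed amount
#' @noRd
shift_features_after <- function(features, at, by) {
  dplyr::mutate(
    features,
    start = ifelse(.data$start >= at, .data$start + by, .data$start),
    end = ifelse(.data$end > at, .data$end + by, .data$end)
  )
}

#' Drop exon rows whose parent gene segment is no longer present
#' @noRd
drop_orphan_exons <- function(features) {
  genes <- features$name[features$kind == "gene_segment"]
  orphan <- features$kind == "exon" & !(features$parent %in% genes)
  features[!orphan, ]
}

#' Coerce a region argument to its bare sequence string
#' @noRd
as_seq <- function(x) {
  if (inherits(x, "annotated_region")) x$seq else as.character(x)
}
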