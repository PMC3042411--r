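#' Dot-matrix plot of window matches
#'
#' @param matches a tibble from [dot_matches()].
#' @param point_size point size passed to `geom_point()`.
#' @return a ggplot object (one point per window match; diagonals mark
#'   conserved blocks, off-diagonals mark repeats).
#' @export
plot_dot_matrix <- function(matches, point_size = 0.2) {
  ggplot2::ggplot(matches, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(size = point_size, shape = 15) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position in sequence A (bp)", y = "position in sequence B (bp)") +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_sperm_panel autoplot method: sperm-by-tag call heatmap.
#' @param object a `sperm_genotypes` tibble.
#' @param ... unused.
#' @export
autoplot.sperm_genotypes <- function(object, ...) {
  tags <- attr(object, "tags") %||% unique(object$tag)
  df <- mutate(as_tibble(object), tag = factor(.data$tag, levels = tags))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tag, y = .data$sperm_id, fill = .data$call)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_manual(values = c(detected = "#2c7fb8", undetected = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn phase_sperm autoplot method: tags-by-haplotype status map.
#' @param object a `sperm_phasing` object.
#' @export
autoplot.sperm_phasing <- function(object, ...) {
  df <- mutate(object$haplotypes, tag = factor(.data$tag, levels = object$tags))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$haplotype, y = .data$tag, fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_manual(
      values = c(`+` = "#31a354", ud = "#de2d26", `-` = "grey60")
    ) +
    ggplot2::labs(
      title = paste("Donor", object$donor), x = NULL, y = NULL, fill = "status"
    ) +
    ggplot2::theme_minimal()
}
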