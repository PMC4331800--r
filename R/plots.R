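#' Plot a sequence-logo matrix
#'
#' Stacked per-position bars with heights proportional to each base's
#' share of the position's information content (the standard logo layout,
#' drawn with bars rather than glyphs).
#'
#' @param object A `logo_matrix` from [information_content()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logo_matrix
#' @export
autoplot.logo_matrix <- function(object, ...) {
  df <- tidy.logo_matrix(object)
  df$height <- df$freq * df$bits
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(
      A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839"
    )) +
    ggplot2::labs(x = "position", y = "information (bits)", fill = NULL) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Plot the genome layout with temporal classes
#'
#' Genes as strand-separated arrows coloured by temporal class, promoters
#' as ticks coloured by promoter class — the layout view used to compare
#' infection strategies between phages.
#'
#' @param genes Gene tibble.
#' @param assignments Tibble from [classify_genes_temporal()].
#' @param promoters Layout tibble with `coordinate`, `strand`, `class`.
#' @return A ggplot object.
#' @export
plot_genome_layout <- function(genes, assignments, promoters = NULL) {
  df <- dplyr::inner_join(genes, assignments, by = "gene_number")
  df$y <- ifelse(df$strand == "+", 1, -1)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y,
                   yend = .data$y, colour = .data$temporal_class),
      linewidth = 4, lineend = "butt"
    ) +
    ggplot2::scale_colour_manual(values = c(
      early = "#2B6CB0", middle = "#B7791F", late = "#C53030",
      unassigned = "grey70"
    )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::scale_y_continuous(breaks = c(-1, 1),
                                labels = c("-", "+"), limits = c(-1.8, 1.8)) +
    ggplot2::labs(x = "genomic coordinate (bp)", y = "strand",
                  colour = "temporal class", shape = "promoter") +
    ggplot2::theme_minimal()
  if (!is.null(promoters) && nrow(promoters) > 0) {
    promoters$y <- ifelse(promoters$strand == "+", 1.45, -1.45)
    p <- p + ggplot2::geom_point(
      data = promoters,
      ggplot2::aes(x = .data$coordinate, y = .data$y, shape = .data$class),
      size = 2.4
    )
  }
  p
}

#' Plot the sigma70 score distribution by strand
#'
#' Visualises the strand positional bias that motivates the reporting
#' threshold: prediction scores on each strand with the selected
#' threshold marked.
#'
#' @param scan Prediction tibble from [scan_genome()] at a permissive
#'   threshold.
#' @param threshold Optional threshold (e.g. from
#'   [threshold_by_strand_bias()]) drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_strand_bias <- function(scan, threshold = NULL) {
  p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$score,
                                          y = .data$strand,
                                          colour = .data$strand)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.7) +
    ggplot2::labs(x = "promoter score (0 = consensus)", y = "strand") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  }
  p
}

#' @method autoplot phage_strategy
#' @export
autoplot.phage_strategy <- function(object, ...) {
  plot_genome_layout(object$genes, object$assignments,
                     object$promoter_layout)
}
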