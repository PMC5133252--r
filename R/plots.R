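subset_palette <- c(preB = "#d7191c", immature = "#fdae61",
                    transitional = "#1a9641", naive = "#2b83ba")

#' Plot PCA scores by cell subset
#'
#' Score plot of the first two principal components, coloured by subset
#' (the conventional red/yellow/green/blue of the developmental series)
#' and annotated with the variance explained.
#'
#' @param object A `rep_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rep_pca <- function(object, ...) {
  df <- object$scores
  evr <- object$explained_variance_ratio
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * evr[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * evr[2])) +
    ggplot2::theme_minimal()
  if ("subset" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$subset), size = 3) +
      ggplot2::scale_colour_manual(values = subset_palette, name = "subset")
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p
}

#' Bubble plot of family-combination usage
#'
#' Mean frequency of each V(D)J family combination per subset; bubble area
#' encodes the mean percent frequency.
#'
#' @param means The `means` element of [combination_tensor()].
#' @return A ggplot.
#' @export
plot_usage_bubbles <- function(means) {
  has_d <- "d_fam" %in% names(means) && !all(is.na(means$d_fam))
  p <- ggplot2::ggplot(means,
    ggplot2::aes(x = factor(.data$j_fam), y = factor(.data$v_fam),
                 size = .data$mean_frequency, colour = .data$subset)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 8, name = "mean %") +
    ggplot2::scale_colour_manual(values = subset_palette, name = "subset") +
    ggplot2::labs(x = "J family", y = "V family") +
    ggplot2::theme_minimal()
  if (has_d) {
    p <- p + ggplot2::facet_grid(subset ~ d_fam,
                                 labeller = ggplot2::label_both)
  } else {
    p <- p + ggplot2::facet_wrap(~subset)
  }
  p
}

#' Plot usage frequencies as grouped bars
#'
#' Mean percent frequency per key with SEM error bars over donors,
#' grouped by subset — the standard family-usage histogram.
#'
#' @param table A `usage_table`.
#' @return A ggplot.
#' @export
plot_usage <- function(table) {
  tab <- as_tibble(table)
  summ <- dplyr::summarise(
    dplyr::group_by(tab, .data$subset, .data$key),
    mean = mean(.data$frequency),
    sem = stats::sd(.data$frequency) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$key, .data$mean,
                                     fill = .data$subset)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::scale_fill_manual(values = subset_palette, name = "subset") +
    ggplot2::labs(x = NULL, y = "frequency (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a Minkowski dendrogram
#'
#' @param x A `rep_dendro`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @exportS3Method base::plot
plot.rep_dendro <- function(x, ...) {
  ape::plot.phylo(x$phylo, ...)
  invisible(x)
}
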