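#' Plot the mean-CV^2 relationship with the fitted trend
#'
#' @param object A `cv2_trend`.
#' @param stats Optional [panel_stats()] tibble to overlay as points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv2_trend <- function(object, stats = NULL, ...) {
  grid <- tidy(object)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$log2_mean, y = .data$log2_cv2_fit))
  if (!is.null(stats)) {
    pts <- dplyr::filter(stats, !is.na(.data$cv2), .data$cv2 > 0, .data$mean > 0)
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = log2(.data$mean), y = log2(.data$cv2)),
      alpha = 0.2, size = 0.5, colour = "grey40"
    )
  }
  p +
    ggplot2::geom_line(colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "log2 mean expression", y = "log2 CV²",
      title = "Mean-variability trend")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin/box plot of a per-gene score by group
#'
#' @param data Tibble with one row per gene.
#' @param score,group Columns to plot (tidy-eval).
#' @return A ggplot.
#' @export
plot_score_groups <- function(data, score, group) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ group }}, y = {{ score }}, fill = {{ group }})) +
    ggplot2::geom_violin(alpha = 0.5, trim = TRUE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.3, fill = "white") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL)
}

#' Scatter of Delta-clade against Delta-score for paralog pairs
#'
#' Each pair appears in both orientations (sign-symmetric), mirroring the
#' arbitrary A/B labelling; pairs with Delta-clade = 0 are excluded.
#'
#' @param divergence Tibble from [pair_divergence()] with clade columns.
#' @param by Faceting column (default `"mode"`).
#' @return A ggplot.
#' @export
plot_age_asymmetry <- function(divergence, by = "mode") {
  check_columns(divergence, c("dclade", "dscore", by), "pair divergence table")
  d <- dplyr::filter(divergence, !is.na(.data$dclade), .data$dclade != 0)
  doubled <- dplyr::bind_rows(
    d,
    dplyr::mutate(d, dclade = -.data$dclade, dscore = -.data$dscore)
  )
  ggplot2::ggplot(doubled, ggplot2::aes(x = .data$dclade, y = .data$dscore)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::facet_wrap(by) +
    ggplot2::labs(x = "Δ clade (A - B)", y = "Δ score (A - B)")
}
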