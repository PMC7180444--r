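#' Plot a B-scan with optional layer boundaries and cyst mask
#'
#' @param image A [bscan()] or numeric matrix.
#' @param boundaries Optional [layer_boundaries()] overlaid as lines.
#' @param cyst_mask Optional logical matrix outlined as points.
#' @return A ggplot object (y axis flipped so depth grows downward).
#' @export
plot_bscan <- function(image, boundaries = NULL, cyst_mask = NULL) {
  img <- as_bscan(image)
  px <- img$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$gray <- as.vector(px)    # expand_grid varies `col` fastest: row-major
  df$gray <- px[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "gray",
                  title = img$id) +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    bd <- tidy(boundaries) |>
      tidyr::pivot_longer(c("ilm_row", "rpe_row"), names_to = "layer",
                          values_to = "row")
    p <- p + ggplot2::geom_line(
      data = bd,
      ggplot2::aes(x = .data$column, y = .data$row, color = .data$layer),
      linewidth = 0.4
    )
  }
  if (!is.null(cyst_mask)) {
    idx <- which(cyst_mask, arr.ind = TRUE)
    if (nrow(idx)) {
      md <- tibble::tibble(row = idx[, 1], col = idx[, 2])
      p <- p + ggplot2::geom_point(data = md, color = "red", size = 0.01,
                                   alpha = 0.1)
    }
  }
  p
}

#' Accuracy curves of a cross-validation run
#'
#' Mean test accuracy against feature-subset size, one line per
#' classifier, faceted by selector.
#'
#' @param object An `oct_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oct_cv <- function(object, ...) {
  curves <- accuracy_curves(object)
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$subset_size, y = .data$mean_accuracy,
    color = .data$classifier
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$selector)) +
    ggplot2::labs(x = "number of top-ranked features",
                  y = "mean CV test accuracy", color = "classifier") +
    ggplot2::theme_minimal()
}

#' Bar chart of selector scores of a feature ranking
#'
#' @param object An `oct_ranking` object.
#' @param top Number of leading features to show (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oct_ranking <- function(object, top = 30L, ...) {
  df <- utils::head(tidy(object), top)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$name)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = paste0(attr(object, "selector"), " score"), y = NULL,
      title = sprintf("top %d of %d ranked features", nrow(df),
                      nrow(object))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of mean absolute correlation between feature categories
#'
#' @param correlation Result of [pairwise_correlation()].
#' @return A ggplot object.
#' @export
plot_category_correlation <- function(correlation) {
  ggplot2::ggplot(correlation$category_means, ggplot2::aes(
    x = .data$category_a, y = .data$category_b,
    fill = .data$mean_abs_correlation
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean |r|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
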