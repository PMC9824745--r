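#' Plot a particle-size distribution
#'
#' Histogram of the summarized metric with the mean marked as a vertical
#' line and the cumulative frequency overlaid as a curve on a secondary
#' axis — the conventional PSD presentation.
#'
#' @param object A `psd_summary` from [psd_histogram()].
#' @param fill Bar fill color.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psd_summary <- function(object, fill = "steelblue", ...) {
  td <- tidy(object)
  cf <- cumulative_frequency(object$values)
  ymax <- max(td$count)
  ggplot2::ggplot(td) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$bin_low, xmax = .data$bin_high,
      ymin = 0, ymax = .data$count),
      fill = fill, color = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$mean, color = "red",
                        linewidth = 0.7) +
    ggplot2::geom_line(data = cf,
                       ggplot2::aes(x = .data$value,
                                    y = .data$cum_pct / 100 * ymax),
                       color = "purple") +
    ggplot2::scale_y_continuous(
      "count",
      sec.axis = ggplot2::sec_axis(~ . / ymax * 100,
                                   name = "cumulative frequency [%]")) +
    ggplot2::labs(
      x = object$metric_name,
      title = sprintf("%s: n = %d, mean = %.3g (SE %.2g)",
                      object$metric_name, object$n_total,
                      object$mean, object$se)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot roundness-class fractions
#'
#' Bar chart of the six-class shape classification with percentage labels.
#'
#' @param fractions Tibble from [class_fractions()].
#' @return A ggplot object.
#' @export
plot_class_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$class, y = .data$percent)) +
    ggplot2::geom_col(fill = "darkorange", color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$percent)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "particles [%]") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Display an image with detected particle outlines
#'
#' Renders the grayscale image and overlays the label map's particle
#' pixels, for a quick visual check of a segmentation.
#'
#' @param image An [image_grid()].
#' @param regions Optional `labeled_regions` to overlay.
#' @return A ggplot object.
#' @export
plot_image <- function(image, regions = NULL) {
  assert_image_grid(image)
  px <- image$pixels
  df <- tibble(
    x = rep(seq_len(ncol(px)) - 1L, each = nrow(px)),
    y = rep(seq_len(nrow(px)) - 1L, times = ncol(px)),
    value = as.vector(px)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(regions)) {
    lm <- regions$label_map
    idx <- which(lm > 0L, arr.ind = TRUE)
    if (nrow(idx) > 0)
      p <- p + ggplot2::geom_point(
        data = tibble(x = idx[, 2] - 1L, y = idx[, 1] - 1L),
        color = "red", size = 0.1, alpha = 0.5)
  }
  p
}
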