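#' Plot a raster grid
#'
#' Renders an RGB orthomosaic or a single-band raster with ggplot2,
#' downsampling large rasters for display.
#'
#' @param object a [raster_grid()].
#' @param max_px maximum displayed pixels along the long side.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.raster_grid <- function(object, max_px = 600, ...) {
  d <- dim(object$values)
  if (max(d[1:2]) > max_px) {
    f <- max(d[1:2]) / max_px
    object <- resize_raster(object, round(d[1] / f), round(d[2] / f))
  }
  d <- dim(object$values)
  df <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
  if (is_rgb(object)) {
    v <- object$values
    df$fill <- grDevices::rgb(v[, , 1], v[, , 2], v[, , 3], maxColorValue = 255)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_raster(fill = df$fill) +
      ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
      ggplot2::theme_void()
  } else {
    v <- object$values
    v[v == object$nodata] <- NA
    df$z <- as.numeric(v)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$z)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "grey80") +
      ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
      ggplot2::labs(fill = "m") + ggplot2::theme_void()
  }
}

#' Map of delineated plots
#'
#' Plot centers and bounding boxes colored by single-row status, drawn in
#' image coordinates (y down).
#'
#' @param plots plot records from [delineate_plots()].
#' @return a ggplot.
#' @export
plot_plot_map <- function(plots) {
  ggplot2::ggplot(plots) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$bbox_x0, xmax = .data$bbox_x0 + .data$bbox_w,
      ymin = .data$bbox_y0, ymax = .data$bbox_y0 + .data$bbox_h,
      color = .data$single_row), fill = NA, linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(.data$center_x, .data$center_y),
                        size = 0.8) +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "single row") +
    ggplot2::theme_minimal()
}

#' Canopy-height distribution
#'
#' @param traits a trait table from [extract_traits()].
#' @param binwidth histogram bin width in cm.
#' @return a ggplot.
#' @export
plot_trait_distribution <- function(traits, binwidth = 2) {
  ggplot2::ggplot(traits, ggplot2::aes(.data$ch_cm)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "forestgreen",
                            color = "white") +
    ggplot2::labs(x = "canopy height (cm)", y = "plots") +
    ggplot2::theme_minimal()
}

#' Accuracy across repeated classifier runs
#'
#' @param object a `trait_classifier`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trait_classifier <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = "", y = .data$accuracy)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, color = "steelblue") +
    ggplot2::labs(x = NULL, y = "test accuracy (%)",
                  title = sprintf("%s / %s / %s", object$trait,
                                  object$spec$model_name,
                                  object$spec$modality)) +
    ggplot2::theme_minimal()
}
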