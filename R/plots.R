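lc_hex_palette <- function() {
  m <- lc_ramp_matrix()
  grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

#' @export
autoplot.lc_histogram <- function(object, ...) {
  pal <- lc_hex_palette()
  fill <- pal[pmin(255L, as.integer(floor(object$midpoint * 256))) + 1L]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$midpoint, y = .data$frequency)) +
    ggplot2::geom_col(fill = fill, width = object$bin_hi - object$bin_lo) +
    ggplot2::labs(x = "local curvature (LC)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Top-view LC heatmap of a cloud
#'
#' Plots the cloud viewed from above, coloured by local curvature on the
#' fixed blue-green-yellow-red ramp (0 = blue, 1 = red; not rescaled to the
#' data, so panels are comparable across plants).
#'
#' @param cloud A cloud with an `lc` column (see [local_curvature()]).
#' @param point_size Point size (default 0.3).
#' @return A ggplot object.
#' @export
plot_lc_heatmap <- function(cloud, point_size = 0.3) {
  if (!"lc" %in% names(cloud)) {
    abort("no `lc` column; run local_curvature() first.",
          class = "leafscan_error_input")
  }
  ggplot2::ggplot(cloud, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$lc)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_colour_gradientn(colours = lc_hex_palette(),
                                    limits = c(0, 1), name = "LC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Trait trajectories over a batch of scans
#'
#' Plots selected trait columns of a [measure()] table against scan order
#' (e.g. a time series of one plant), one facet per trait -- the classic
#' growth-monitoring panel: height, projected area, voxel volume,
#' compactness and LC-histogram centroid.
#'
#' @param records A [measure()] result.
#' @param traits Character vector of trait columns to plot.
#' @param time Optional numeric vector (e.g. days after sowing); defaults to
#'   scan order.
#' @return A ggplot object.
#' @export
plot_trait_series <- function(records,
                              traits = c("height", "projected_area",
                                         "voxel_volume", "compactness",
                                         "lcg"),
                              time = NULL) {
  missing_cols <- setdiff(traits, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("unknown trait column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "leafscan_error_input")
  }
  df <- records[, c("id", traits)]
  df$.time <- time %||% seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(traits),
                              names_to = "trait", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "scan", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.angle_bench <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$angle)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = NA) +
    ggplot2::labs(x = "estimated cell angle (deg)", y = "cells") +
    ggplot2::theme_minimal()
}
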