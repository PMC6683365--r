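# Lightweight ggplot2 figure helpers for the analysis drivers.  ggplot2 is
# a suggested dependency; each function checks for it at call time.

#' Plot an ion image or corrected log image as a heatmap
#'
#' @param image an [ion_image()] or [log_ion_image()].
#' @param limits optional shared colour-scale limits (use one scale across
#'   samples when comparing sections of one ion).
#' @return A ggplot object.
#' @export
plot_ion_image <- function(image, limits = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  v <- image$values
  df <- expand.grid(y = seq_len(nrow(v)), x = seq_len(ncol(v)))
  df$value <- as.vector(v)
  lab <- if (is.na(image$target_mz)) "TIC" else {
    sprintf("m/z %g", image$target_mz)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = limits, na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s)", image$sample_id, lab),
                  fill = if (inherits(image, "log_ion_image"))
                    "log10 I" else "I") +
    ggplot2::theme_minimal()
}

#' Plot a distance-from-border profile
#'
#' @param profile tibble from [bin_by_distance()].
#' @param sample_id title label.
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(profile, sample_id = "") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(profile[!is.na(profile$median_signal), ],
                  ggplot2::aes(x = .data$dist_mid, y = .data$median_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pixels)) +
    ggplot2::labs(x = "distance from tissue border (pixels)",
                  y = "median corrected log10 intensity",
                  title = sample_id, size = "pixels") +
    ggplot2::theme_minimal()
}
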