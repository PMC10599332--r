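#' Plot an ROI attenuation histogram
#'
#' Bars of counts per attenuation bin with the smoothed-peak location
#' marked, mirroring the histogram-comparison figure style of stain
#' quantification.
#'
#' @param object A `histogram_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot histogram_result
#' @export
autoplot.histogram_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_edges)[1], fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$peak_value, colour = "red") +
    ggplot2::labs(x = "attenuation (1/vox)", y = "counts",
                  subtitle = sprintf("peak at %.4g /vox", object$peak_value)) +
    ggplot2::theme_minimal()
}

#' Plot a slice of a reconstructed volume
#'
#' @param volume A `recon_volume`.
#' @param z Slice index (default: central slice).
#' @return A ggplot raster plot.
#' @export
plot_slice <- function(volume, z = NULL) {
  stopifnot(inherits(volume, "recon_volume"))
  d <- dim(volume$values)
  if (is.null(z)) z <- max(1L, (d[3] + 1L) %/% 2L)
  sl <- volume$values[, , z]
  df <- expand.grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = volume$units) +
    ggplot2::theme_void()
}

#' Plot delta/beta ratio energy scans
#'
#' @param scan A tibble from [delta_beta_scan()].
#' @return A ggplot object with one line per element on a log y scale.
#' @export
plot_delta_beta_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$energy, y = .data$delta_beta,
                                     colour = .data$symbol)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "photon energy (keV)", y = expression(delta / beta),
                  colour = "element") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
NULL
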