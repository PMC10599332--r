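#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stain-quantification report
#'
#' One row per report with the measured excess attenuation and the derived
#' densities.
#'
#' @param x A `quant_report` from [quantify_stain()].
#' @param ... Unused.
#' @return A tibble with columns `element`, `energy`, `delta_mu`,
#'   `f2_used`, `number_density`, `mass_density`, `mean_distance`.
#' @method tidy quant_report
#' @export
tidy.quant_report <- function(x, ...) {
  tibble::tibble(
    element = x$element,
    energy = x$energy,
    delta_mu = x$delta_mu,
    f2_used = x$f2_used,
    number_density = x$density$number_density,
    mass_density = x$density$mass_density,
    mean_distance = x$density$mean_distance
  )
}

#' @rdname tidy.quant_report
#' @method glance quant_report
#' @export
glance.quant_report <- function(x, ...) {
  tibble::tibble(
    element = x$element,
    energy = x$energy,
    voxel_size = x$voxel_size,
    n_roi = x$histograms$stained$n,
    bin_width = x$histograms$stained$smoothing$bin_width,
    negative_delta_mu = x$negative
  )
}

#' Tidy an ROI histogram
#'
#' @param x A `histogram_result` from [roi_histogram()].
#' @param ... Unused.
#' @return A tibble with `bin_center` and `count`.
#' @method tidy histogram_result
#' @export
tidy.histogram_result <- function(x, ...) {
  tibble::tibble(
    bin_center = x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2,
    count = x$counts
  )
}

#' Tidy a scattering table
#'
#' @param x A [scattering_table()].
#' @param ... Unused.
#' @return A tibble with `symbol`, `energy`, `f1`, `f2`, `delta_beta`.
#' @method tidy scattering_table
#' @export
tidy.scattering_table <- function(x, ...) {
  tibble::tibble(symbol = x$symbol, energy = x$rows$energy,
                 f1 = x$rows$f1, f2 = x$rows$f2,
                 delta_beta = x$rows$f1 / x$rows$f2)
}
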