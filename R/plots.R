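## ggplot2 visualizations for spectra, depth-dose tables, dose maps and
## region histograms.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an x-ray spectrum
#'
#' @param object an `xray_spectrum`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot xray_spectrum
#' @export
autoplot.xray_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$energy_keV, y = .data$fluence)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Energy (keV)", y = "Relative photon fluence") +
    ggplot2::theme_minimal()
}

#' Plot a depth-dose table
#'
#' Mean position dose versus depth with the position spread as error
#' bars.
#'
#' @param object a `depth_dose_table`.
#' @param ... unused.
#' @method autoplot depth_dose_table
#' @export
autoplot.depth_dose_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_cm,
                                       y = .data$mean_dose)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_dose - .data$sd_dose,
      ymax = .data$mean_dose + .data$sd_dose)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Depth (cm)", y = "Mean dose") +
    ggplot2::theme_minimal()
}

#' Plot a simulated 2D dose map
#'
#' @param result an `mc_result` carrying a `map` element.
#' @param scale multiplicative factor applied to the per-history doses
#'   (e.g. a [scale_factor()] for absolute mGy).
#' @export
plot_dose_map <- function(result, scale = 1) {
  if (is.null(result$map)) {
    abort("result carries no dose map", class = "mammodose_analysis")
  }
  m <- result$map
  df <- tidyr::expand_grid(ix = seq_along(m$x_mm), iy = seq_along(m$y_mm))
  df$x_mm <- m$x_mm[df$ix]
  df$y_mm <- m$y_mm[df$iy]
  df$dose <- m$dose_per_history_mGy[cbind(df$ix, df$iy)] * scale
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Dose") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a dose-value region histogram
#'
#' Histogram normalized to unit maximum, with the region thresholds as
#' dashed lines.
#'
#' @param object a `region_histogram`.
#' @param ... unused.
#' @method autoplot region_histogram
#' @export
autoplot.region_histogram <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$mid, .data$normalized)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$thresholds, linetype = "dashed") +
    ggplot2::labs(x = "Dose (mGy)", y = "Normalized frequency") +
    ggplot2::theme_minimal()
}
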