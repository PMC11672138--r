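# ggplot2 displays for spectra, trajectories, fit reports and the blueshift
# surface.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object A `vsm_spectrum`.
#' @param ... Unused.
#' @return A ggplot object: intensity against wavenumber with detected
#'   peaks marked.
#' @method autoplot vsm_spectrum
#' @export
autoplot.vsm_spectrum <- function(object, ...) {
  pk <- attr(object, "peaks")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$wavenumber,
                                    y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("wavenumber (cm"^-1 * ")"),
                  y = "intensity (a.u.)")
  if (nrow(pk))
    p <- p + ggplot2::geom_vline(xintercept = pk$position,
                                 linetype = "dashed", colour = "red3")
  p
}

#' Plot a probe trajectory
#'
#' @param object A `probe_trajectory`.
#' @param n_show Number of leading frames to display.
#' @param ... Unused.
#' @return A ggplot object: instantaneous frequency against time, colored
#'   by hydrogen-bond occupancy.
#' @method autoplot probe_trajectory
#' @export
autoplot.probe_trajectory <- function(object, n_show = 5000, ...) {
  df <- utils::head(tibble::as_tibble(object), n_show)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_fs / 1000,
                                   y = .data$frequency,
                                   colour = factor(.data$hb_state))) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "time (ps)", y = expression("frequency (cm"^-1 * ")"),
                  colour = "H-bonded")
}

#' Observed-versus-predicted plot for a fit report
#'
#' @param object A fit object from one of the `fit_*()` functions.
#' @param ... Unused.
#' @return A ggplot object with the identity line.
#' @method autoplot vsemap_fit
#' @export
autoplot.vsemap_fit <- function(object, ...) {
  df <- tibble::tibble(predicted = object$fitted,
                       observed = object$fitted + object$residuals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed,
                                   y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "observed", y = "modeled")
}

#' Heat map of the hydrogen-bond blueshift surface
#'
#' @param params A [blueshift_params()] object.
#' @param d_range,theta_range Plotted geometry ranges.
#' @param n Grid points per axis.
#' @return A ggplot raster of the blueshift over distance and angle.
#' @export
plot_blueshift_surface <- function(params = blueshift_params(),
                                   d_range = c(2.5, 5), theta_range = c(70, 175),
                                   n = 120) {
  grid <- tidyr::expand_grid(
    d = seq(d_range[1], d_range[2], length.out = n),
    theta = seq(theta_range[1], theta_range[2], length.out = n))
  grid <- predict_blueshift(grid, params)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$d, y = .data$theta,
                                     fill = .data$blueshift)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * bar(nu)[HB] *
                                                      " (cm"^-1 * ")")) +
    ggplot2::labs(x = "heavy-atom HB distance d (Å)",
                  y = "HB angle θ (deg)")
}
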