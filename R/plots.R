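#' Plot methods
#'
#' `autoplot()` methods for the package's result objects and
#' [plot_agreement()] for observed-vs-predicted evaluation, all returning
#' ggplot objects for further styling.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name wormkin_plots
NULL

#' @describeIn wormkin_plots Body-residue time course.
#' @export
autoplot.kinetic_solution <- function(object, ...) {
  p <- attr(object, "params")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$c_earthworm)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (d)", y = "body residue (mg/kg ww)",
                  title = sprintf("kin = %.3g, kout = %.3g 1/d",
                                  p$kin, p$kout)) +
    ggplot2::theme_minimal()
}

#' @describeIn wormkin_plots Observed points and fitted uptake curve of a
#'   [fit_kinetics_to_timeseries()] result.
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  grid <- tibble::tibble(time = seq(0, max(object$data$time), length.out = 200))
  grid$fitted <- closed_form_cw(object$kin, object$kout, object$c0,
                                object$k0, grid$time)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fitted), color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (d)", y = "body residue (mg/kg ww)",
                  title = sprintf("kin = %.3g, kout = %.3g 1/d (%s route)",
                                  object$kin, object$kout, object$route)) +
    ggplot2::theme_minimal()
}

#' @describeIn wormkin_plots Applicability-domain report: descriptor ranges
#'   with the checked values, colored by status.
#' @export
autoplot.domain_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(y = .data$descriptor)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low, xend = .data$high,
                                       yend = .data$descriptor),
                          color = "grey60", linewidth = 3, alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(x = .data$value, color = .data$status),
                        size = 3) +
    ggplot2::scale_color_manual(values = c(inside = "forestgreen",
                                           below = "firebrick",
                                           above = "firebrick")) +
    ggplot2::labs(x = "value (descriptor units)", y = NULL,
                  title = "applicability domain") +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted agreement plot
#'
#' Log-log scatter with the 1:1 line and factor-of-N bands, the standard
#' display for bioaccumulation model evaluation.
#'
#' @param data Data frame of paired values.
#' @param observed,predicted Column names (strings); values must be > 0.
#' @param factors Fold-difference bands to draw.
#' @param color Optional column name used to color points.
#' @return A ggplot.
#' @export
plot_agreement <- function(data, observed = "observed",
                           predicted = "predicted",
                           factors = c(3, 5, 10), color = NULL) {
  bands <- tidyr::expand_grid(factor = factors, side = c(1, -1))
  aes_pt <- if (is.null(color))
    ggplot2::aes(x = .data[[observed]], y = .data[[predicted]])
  else
    ggplot2::aes(x = .data[[observed]], y = .data[[predicted]],
                 color = .data[[color]])
  ggplot2::ggplot(data, aes_pt) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(
      data = bands,
      ggplot2::aes(slope = 1, intercept = .data$side * log10(.data$factor),
                   linetype = base::factor(.data$factor)),
      color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observed (mg/kg ww)", y = "predicted (mg/kg ww)",
                  linetype = "factor") +
    ggplot2::theme_minimal()
}
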