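#' Plot a molecule pool's species distribution
#'
#' @param object A [molecule_pool()].
#' @param ... Unused.
#' @return A ggplot bar chart of the four species fractions.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.molecule_pool <- function(object, ...) {
  df <- measure_all(object)
  df$species <- factor(df$species, levels = c("unnicked", "nickA", "nickB", "both"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of pool",
                  title = sprintf("Pool species (%s mode)", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a seesaw gate's activation response
#'
#' Shows the stoichiometric step endpoint and, optionally, the smooth
#' logistic relaxation.
#'
#' @param object A [seesaw_gate()].
#' @param smooth_slope When non-`NULL`, overlay [seesaw_activate_smooth()]
#'   with this slope.
#' @param ... Unused.
#' @return A ggplot of output vs input fraction.
#' @export
autoplot.seesaw_gate <- function(object, smooth_slope = NULL, ...) {
  u <- seq(0, 1, by = 0.001)
  df <- tibble::tibble(u = u, output = seesaw_activate(u, object),
                       form = "step (endpoint)")
  if (!is.null(smooth_slope)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      u = u, output = seesaw_activate_smooth(u, object, smooth_slope),
      form = sprintf("logistic (slope %g)", smooth_slope)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$output,
                                   colour = .data$form)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "input ssDNA fraction u", y = "output fraction",
                  colour = NULL,
                  title = sprintf("Seesaw activation (threshold %g, cap %g)",
                                  object$threshold,
                                  min(object$replenishment_cap, object$gate_supply))) +
    ggplot2::theme_minimal()
}

#' Plot a latency calibration fit
#'
#' Calibration points with the fitted affine delay law
#' `delay = factor * A + B`.
#'
#' @param object A [calibrate_timing()] fit.
#' @param factors Serialization factors at which to draw the line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.timing_fit <- function(object, factors = NULL, ...) {
  pts <- object$points
  factors <- factors %||% seq(1, max(pts$factor) * 2)
  line <- tibble::tibble(factor = factors,
                         delay_hours = factors * object$A + object$B)
  ggplot2::ggplot(line, ggplot2::aes(x = .data$factor, y = .data$delay_hours)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = pts, colour = "firebrick", size = 2) +
    ggplot2::labs(x = "serialization factor", y = "layer delay (h)",
                  title = sprintf("delay = %.3f x factor + %.3f h",
                                  object$A, object$B)) +
    ggplot2::theme_minimal()
}

#' Plot a configuration performance report
#'
#' Per-configuration layer delay and (log-scale) array area.
#'
#' @param object A [config_report()] tibble.
#' @param ... Unused.
#' @return A ggplot with delay bars and area points on a secondary panel.
#' @export
autoplot.config_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object,
    c("area_pessimistic_cm2", "area_optimistic_cm2", "delay_hours"),
    names_to = "metric", values_to = "value")
  long$metric <- dplyr::recode(long$metric,
    area_pessimistic_cm2 = "area, pessimistic (cm2)",
    area_optimistic_cm2 = "area, optimistic (cm2)",
    delay_hours = "delay per layer (h)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$configuration, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Device configurations: area vs per-layer delay") +
    ggplot2::theme_minimal()
}
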