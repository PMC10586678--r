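#' Timing parameters of the lab-on-chip latency model
#'
#' The factor-1 layer latency decomposes into transport, multiplication
#' (second nicking), row merge and activation stages, with the activation
#' itself split into displacement, threshold, gate, translation and nicking
#' times. The serialized model groups these into a per-pass part
#' `A = t_transport + t_mult` (repeated once per serialization pass) and a
#' fixed part `B = t_merge + t_activation`:
#' `t_layer = ceiling(k_layer / k_physical) * A + B`.
#'
#' Only the totals A and B are identifiable from published latency points
#' (see [calibrate_timing()]); of the individual stages only the transport
#' time (about 2 minutes) has an independent estimate. The remaining defaults
#' split A and B transparently as `t_mult = A - t_transport`, `t_merge = 0`
#' and all of B in `t_gate`, and are flagged `unconstrained`.
#'
#' @param t_transport Droplet transport time per pass, hours (default 2/60).
#' @param t_mult Second-nicking (multiplication) time, hours.
#' @param t_merge Row-merge time, hours.
#' @param t_displacement,t_threshold,t_gate,t_translation,t_nick Activation
#'   stage times, hours.
#' @param unconstrained Whether the stage split beyond A and B is
#'   unconstrained by data (default `TRUE` unless all stages are supplied).
#' @return An object of class `timing_params` with derived `t_activation`,
#'   `A` and `B`.
#' @export
timing_params <- function(t_transport = 2 / 60, t_mult = 2, t_merge = 0,
                          t_displacement = 0, t_threshold = 0, t_gate = 6,
                          t_translation = 0, t_nick = 0,
                          unconstrained = TRUE) {
  stages <- c(t_transport = t_transport, t_mult = t_mult, t_merge = t_merge,
              t_displacement = t_displacement, t_threshold = t_threshold,
              t_gate = t_gate, t_translation = t_translation, t_nick = t_nick)
  if (any(stages < 0)) stop("stage times must be nonnegative", call. = FALSE)
  t_activation <- t_displacement + t_threshold + t_gate + t_translation + t_nick
  structure(
    c(as.list(stages),
      list(t_activation = t_activation,
           A = t_transport + t_mult,
           B = t_merge + t_activation,
           unconstrained = unconstrained)),
    class = "timing_params"
  )
}

#' @export
print.timing_params <- function(x, ...) {
  cat(sprintf("<timing_params: A = %.4f h/pass, B = %.4f h%s>\n", x$A, x$B,
              if (isTRUE(x$unconstrained)) " (stage split unconstrained)" else ""))
  invisible(x)
}

#' Published latency calibration points
#'
#' The two printed layer latencies that pin down the serialized delay model:
#' 8.07 hours for a full-width (factor-1) layer and 14.17 hours for the same
#' layer serialized by a factor of 4.
#'
#' @return A tibble with columns `factor` and `delay_hours`.
#' @export
reference_delay_points <- function() {
  tibble::tibble(factor = c(1, 4), delay_hours = c(8.07, 14.17))
}

#' Calibrate the per-pass and fixed latency constants
#'
#' Least-squares solve of `delay = factor * A + B` over latency points. With
#' the two exact published points (factor 1, 8.07 h) and (factor 4, 14.17 h)
#' this gives `A = (14.17 - 8.07) / 3` and `B = 8.07 - A`.
#'
#' @param points A data frame with columns `factor` and `delay_hours` (at
#'   least two rows with distinct factors).
#' @return An object of class `timing_fit` with elements `A`, `B`, the `lm`
#'   fit and the input points; usable wherever a [timing_params()] is.
#' @examples
#' fit <- calibrate_timing(reference_delay_points())
#' fit$A # 2.0333
#' @export
calibrate_timing <- function(points = reference_delay_points()) {
  points <- tibble::as_tibble(points)
  if (!all(c("factor", "delay_hours") %in% names(points))) {
    stop("`points` needs columns `factor` and `delay_hours`", call. = FALSE)
  }
  if (length(unique(points$factor)) < 2L) {
    stop("calibration error: need at least two points with distinct factors",
         call. = FALSE)
  }
  fit <- stats::lm(delay_hours ~ factor, data = points)
  structure(
    list(A = unname(stats::coef(fit)[["factor"]]),
         B = unname(stats::coef(fit)[["(Intercept)"]]),
         model = fit, points = points),
    class = "timing_fit"
  )
}

#' @export
print.timing_fit <- function(x, ...) {
  cat(sprintf("<timing_fit: A = %.4f h/pass, B = %.4f h (from %d points)>\n",
              x$A, x$B, nrow(x$points)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
#' @rdname timing_fit_methods
#' @param x A `timing_fit`.
#' @param ... Unused.
tidy.timing_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("B (fixed, h)", "A (per pass, h)"),
    estimate = c(x$B, x$A),
    std.error = unname(s[, "Std. Error"])
  )
}

#' Broom-style summaries of a latency calibration
#'
#' `tidy()` gives the estimated per-pass slope A and fixed offset B with
#' standard errors; `glance()` the fit-level summary.
#'
#' @name timing_fit_methods
NULL

#' @importFrom generics glance
#' @export
#' @rdname timing_fit_methods
glance.timing_fit <- function(x, ...) {
  tibble::tibble(
    A = x$A, B = x$B, n_points = nrow(x$points),
    sigma = summary(x$model)$sigma,
    factor1_delay_hours = x$A + x$B
  )
}

#' Default calibrated timing
#'
#' [timing_params()] with A and B fixed by [calibrate_timing()] on the two
#' published latency points and the stage split chosen per the documented
#' convention (`t_transport` = 2 min, `t_mult = A - t_transport`,
#' `t_merge = 0`, activation carries all of B).
#'
#' @return A `timing_params`.
#' @export
default_timing <- function() {
  fit <- calibrate_timing(reference_delay_points())
  t_transport <- 2 / 60
  timing_params(t_transport = t_transport, t_mult = fit$A - t_transport,
                t_merge = 0, t_gate = fit$B, unconstrained = TRUE)
}

#' Serialized per-layer delay
#'
#' `t_layer = ceiling(k_layer / k_physical) * (t_transport + t_mult) +
#' t_merge + t_activation`. With factor 1 this reduces to the plain
#' stage-sum latency.
#'
#' @param p A [timing_params()] or [calibrate_timing()] fit (anything with
#'   `A` and `B`).
#' @param k_layer Number of neurons in the layer (>= 1).
#' @param k_physical Array dimension (>= 1).
#' @return Delay in hours.
#' @examples
#' layer_delay(default_timing(), 784, 196) # 14.17
#' @export
layer_delay <- function(p, k_layer, k_physical) {
  stopifnot(k_layer >= 1, k_physical >= 1)
  if (is.null(p$A) || is.null(p$B) || p$A < 0 || p$B < 0) {
    stop("timing parameters must provide nonnegative A and B", call. = FALSE)
  }
  ceiling(k_layer / k_physical) * p$A + p$B
}

layer_elapsed <- function(p, k_layer, k_physical) {
  f <- ceiling(k_layer / k_physical)
  tibble::tibble(
    component = c("transport+mult (per pass)", "merge+activation (fixed)",
                  "total"),
    passes = c(f, 1, NA),
    hours = c(f * p$A, p$B, f * p$A + p$B)
  )
}

#' Area parameters of the microcell array
#'
#' The array footprint scales quadratically with the array dimension:
#' `W = (m * c * k)^2` for channel width `c` and a cell side of `m` channel
#' widths. The pessimistic fabrication estimate uses `c = 0.2` mm and
#' `m = 6` (two channel tracks per axis plus a separation track, each twice
#' a channel wide), giving 1.44 mm^2 per cell; the optimistic estimate uses
#' `c = 0.035` mm and `m = 3`, published rounded to 0.01 mm^2 per cell (the
#' exact (3 * 0.035)^2 = 0.011025 is available via `use_printed = FALSE`).
#'
#' @param channel_width_mm Channel width `c` in mm.
#' @param cell_multiplier Channel widths per cell side `m` (6 pessimistic,
#'   3 optimistic).
#' @param per_cell_coefficient Optional override of the mm^2-per-cell
#'   coefficient (otherwise `(m * c)^2`).
#' @return An object of class `area_params`.
#' @export
area_params <- function(channel_width_mm = 0.2, cell_multiplier = 6,
                        per_cell_coefficient = NULL) {
  if (channel_width_mm <= 0) stop("`channel_width_mm` must be positive", call. = FALSE)
  if (cell_multiplier <= 0) stop("`cell_multiplier` must be positive", call. = FALSE)
  coef <- per_cell_coefficient %||%
    (cell_multiplier * channel_width_mm)^2
  structure(list(channel_width_mm = channel_width_mm,
                 cell_multiplier = cell_multiplier,
                 per_cell_coefficient = coef),
            class = "area_params")
}

#' @rdname area_params
#' @export
area_pessimistic <- function() area_params(0.2, 6)

#' @rdname area_params
#' @param use_printed Use the published rounded 0.01 mm^2 coefficient
#'   (default) rather than the exact (3 * 0.035)^2.
#' @export
area_optimistic <- function(use_printed = TRUE) {
  if (use_printed) area_params(0.035, 3, per_cell_coefficient = 0.01)
  else area_params(0.035, 3)
}

#' Microcell array area
#'
#' `area = per_cell_coefficient * k^2`, optionally converted to cm^2 and
#' rounded.
#'
#' @param k Array dimension.
#' @param p An [area_params()].
#' @param units `"mm2"` or `"cm2"`.
#' @param decimals Optional rounding.
#' @return Area in the requested units.
#' @examples
#' array_area(196, area_pessimistic(), "cm2", 2) # 553.19
#' @export
array_area <- function(k, p = area_pessimistic(), units = c("mm2", "cm2"),
                       decimals = NULL) {
  stopifnot(k >= 1)
  units <- match.arg(units)
  a <- p$per_cell_coefficient * k^2
  if (units == "cm2") a <- a / 100
  if (!is.null(decimals)) a <- round(a, decimals)
  a
}

# round to the table's printed precision: 2 decimals, falling back to 3
# when 2 would print a positive value as zero
round_printed <- function(x, decimals = 2L) {
  r <- round(x, decimals)
  ifelse(r == 0 & x > 0, round(x, decimals + 1L), r)
}

#' Device configuration presets
#'
#' The four published device configurations: array dimensions 196, 49, 16
#' and 4, whose 784-wide layers are serialized by factors 4, 16, 49 and 196.
#'
#' @param layer_width Width of the layer the factors refer to (default 784,
#'   a 28 x 28 input frame).
#' @return A tibble with `configuration`, `k_physical` and `factor`.
#' @export
config_presets <- function(layer_width = 784L) {
  k <- c(196L, 49L, 16L, 4L)
  tibble::tibble(
    configuration = paste0("Config-", 1:4),
    k_physical = k,
    factor = as.integer(ceiling(layer_width / k))
  )
}

#' Performance report across device configurations
#'
#' Recomputes, for each configuration, the microcell count, the pessimistic
#' and optimistic array areas (rounded to the printed precision) and the
#' serialized per-layer execution time for a `layer_width`-wide layer from
#' the calibrated delay model.
#'
#' @param timing A [timing_params()] or [calibrate_timing()] fit.
#' @param layer_width Layer width the delays refer to (default 784).
#' @param presets A preset tibble from [config_presets()].
#' @return A tibble of class `config_report` with one row per configuration:
#'   `configuration`, `k_physical`, `microcells`, `factor`,
#'   `area_pessimistic_cm2`, `area_optimistic_cm2`, `delay_hours`.
#' @examples
#' config_report()
#' @export
config_report <- function(timing = default_timing(), layer_width = 784L,
                          presets = config_presets(layer_width)) {
  out <- dplyr::mutate(
    presets,
    microcells = sprintf("%d x %d", .data$k_physical, .data$k_physical),
    area_pessimistic_cm2 = round_printed(
      array_area(.data$k_physical, area_pessimistic(), "cm2")),
    area_optimistic_cm2 = round_printed(
      array_area(.data$k_physical, area_optimistic(), "cm2")),
    delay_hours = vapply(.data$k_physical, function(k) {
      layer_delay(timing, k_layer = layer_width, k_physical = k)
    }, numeric(1))
  )
  out <- dplyr::relocate(out, "configuration", "k_physical", "microcells",
                         "factor")
  class(out) <- c("config_report", class(out))
  out
}
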