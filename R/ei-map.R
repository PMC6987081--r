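#' Map a shear-stress field to an elongation-index field
#'
#' Applies an EI(SS) calibration cell-wise to the local shear-stress
#' magnitude `tau = mu * gamma_dot` of a solved flow field, giving the
#' spatial distribution of red-cell elongation. The fitted function is
#' extrapolated outside the measured 0.3-50 Pa ladder (the simulated
#' lumen contains stresses below the lowest measured level); the number
#' of nodes falling below/above the fit domain is recorded rather than
#' clamped.
#'
#' @param field A `flow_field` from [solve_steady()] or one phase of
#'   [solve_pulsatile()].
#' @param cal An [ei_calibration()].
#' @return An object of class `ei_field`: the EI matrix on the same grid,
#'   condition and calibration labels, clamp metadata and time stamp.
#' @examples
#' prob <- flow_problem(channel_geometry(), inlet = 0.3, nx = 8, ny = 32)
#' ei <- map_ei(solve_steady(prob), cal_preset("eq1_oxygenated"))
#' range(ei$ei)
#' @export
map_ei <- function(field, cal) {
  stopifnot(inherits(field, "flow_field"), inherits(cal, "ei_calibration"))
  tau <- field$tau
  ei <- matrix(predict(cal, as.vector(tau)), nrow(tau), ncol(tau))
  structure(
    list(
      ei = ei,
      x = field$x, y = field$y,
      mask = field$mask,
      condition = cal$condition,
      calibration = cal$name,
      n_below_domain = sum(tau < cal$fit_domain[1]),
      n_above_domain = sum(tau > cal$fit_domain[2]),
      time = field$time,
      geometry = field$geometry
    ),
    class = "ei_field"
  )
}

#' @rdname map_ei
#' @param series A `flow_series`.
#' @return `map_ei_series()`: list of `ei_field`, one per stored phase.
#' @export
map_ei_series <- function(series, cal) {
  stopifnot(inherits(series, "flow_series"))
  purrr::map(series$fields, map_ei, cal = cal)
}

#' @export
print.ei_field <- function(x, ...) {
  cat("<ei_field>", x$condition, sprintf("(%s), t = %g s\n",
                                         x$calibration, x$time))
  cat(sprintf("  EI range [%.4f, %.4f]; %d nodes below / %d above fit domain\n",
              min(x$ei), max(x$ei), x$n_below_domain, x$n_above_domain))
  invisible(x)
}

#' @rdname map_ei
#' @param x An `ei_field`.
#' @param ... Unused.
#' @method tidy ei_field
#' @export
tidy.ei_field <- function(x, ...) {
  grid <- expand.grid(y_m = x$y, x_m = x$x, KEEP.OUT.ATTRS = FALSE)
  tibble(x_m = grid$x_m, y_m = grid$y_m, ei = as.vector(x$ei),
         condition = x$condition, time_s = x$time)
}

#' @rdname map_ei
#' @param object An `ei_field`.
#' @method autoplot ei_field
#' @export
autoplot.ei_field <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$x_m, .data$y_m, fill = .data$ei)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "EI") +
    ggplot2::coord_fixed(ratio = 2) +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("Elongation index, %s (t = %g s)",
                                  object$condition, object$time))
}

#' Wall-to-centre elongation ratio
#'
#' Ratio of the mean EI in a near-wall band to the mean EI in a band
#' around the centreline, the summary used to quantify how much more
#' elongated cells are near the vessel wall than in the lumen core. Band
#' widths default to 10% of the half-height/radius on each side.
#'
#' @param x An `ei_field`, or a list of `ei_field` (e.g. from
#'   [map_ei_series()]).
#' @param band Fractional band width (default 0.1).
#' @param ... Unused.
#' @return For a single field, a one-row tibble with `time_s`, `ratio`,
#'   `mean_wall_ei`, `mean_center_ei`; for a list, one row per phase plus
#'   attributes `ratio_min` / `ratio_max` over the period.
#' @export
wall_center_ratio <- function(x, band = 0.1, ...) {
  UseMethod("wall_center_ratio")
}

#' @export
wall_center_ratio.ei_field <- function(x, band = 0.1, ...) {
  check_number(band, "band", lower = 1e-6, upper = 0.5)
  span <- geometry_span(x$geometry)
  dist_from_axis <- if (x$geometry$type == "channel") abs(x$y) else x$y
  wall_rows <- dist_from_axis >= (1 - band) * span
  center_rows <- dist_from_axis <= band * span
  if (!any(wall_rows) || !any(center_rows)) {
    abort("Empty wall or centre band; increase `band` or grid resolution.",
          class = "oxyshear_geometry_error")
  }
  mean_wall <- mean(x$ei[wall_rows, ])
  mean_center <- mean(x$ei[center_rows, ])
  tibble(time_s = x$time, ratio = mean_wall / mean_center,
         mean_wall_ei = mean_wall, mean_center_ei = mean_center)
}

#' @export
wall_center_ratio.list <- function(x, band = 0.1, ...) {
  out <- purrr::list_rbind(purrr::map(x, wall_center_ratio, band = band))
  attr(out, "ratio_min") <- min(out$ratio)
  attr(out, "ratio_max") <- max(out$ratio)
  out
}

#' Compare oxygenated and deoxygenated EI fields
#'
#' Per-node difference map (deoxygenated minus oxygenated) with global
#' extrema of each field and the fraction of nodes where the
#' deoxygenated EI exceeds the oxygenated EI (1 with the built-in
#' presets, whose curves are ordered pointwise).
#'
#' @param ei_oxy,ei_deoxy `ei_field` objects on the same grid and time.
#' @return A list with `diff` (matrix), and `summary`, a one-row tibble:
#'   `min_oxy`, `max_oxy`, `min_deoxy`, `max_deoxy`, `fraction_deoxy_higher`,
#'   `mean_diff`, `time_s`.
#' @export
compare_conditions <- function(ei_oxy, ei_deoxy) {
  stopifnot(inherits(ei_oxy, "ei_field"), inherits(ei_deoxy, "ei_field"))
  if (!identical(dim(ei_oxy$ei), dim(ei_deoxy$ei)) ||
      !identical(ei_oxy$mask, ei_deoxy$mask)) {
    abort("EI fields are on different grids or masks.",
          class = "oxyshear_shape_error")
  }
  if (!isTRUE(all.equal(ei_oxy$time, ei_deoxy$time))) {
    abort("EI fields are at different times.", class = "oxyshear_shape_error")
  }
  d <- ei_deoxy$ei - ei_oxy$ei
  list(
    diff = d,
    summary = tibble(
      min_oxy = min(ei_oxy$ei), max_oxy = max(ei_oxy$ei),
      min_deoxy = min(ei_deoxy$ei), max_deoxy = max(ei_deoxy$ei),
      fraction_deoxy_higher = mean(d > 0),
      mean_diff = mean(d),
      time_s = ei_oxy$time
    )
  )
}
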