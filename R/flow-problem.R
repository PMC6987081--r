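#' Sinusoidal inlet pulse
#'
#' Time-varying inlet mean velocity approximating a physiological pulse:
#' \deqn{v(t) = \frac{v_{min}+v_{max}}{2} +
#'       \frac{v_{max}-v_{min}}{2}\sin(2\pi t/T).}
#' Defaults are the diastolic/systolic velocities 0.1 and 0.5 m/s with a
#' 0.5 s period (120 beats per minute). Phase zero is at the ascending
#' mean, a deterministic choice since only the extremes and period are
#' physiologically constrained.
#'
#' @param v_min,v_max Diastolic and systolic inlet velocities (m/s),
#'   `v_max > v_min > 0`.
#' @param period Pulse period (s), > 0.
#' @return An object of class `pulse_profile`.
#' @examples
#' p <- pulse_profile()
#' inlet_velocity(p, c(0, 0.125, 0.25))
#' @export
pulse_profile <- function(v_min = 0.1, v_max = 0.5, period = 0.5) {
  check_positive(v_min, "v_min")
  check_positive(v_max, "v_max")
  check_positive(period, "period")
  if (v_max <= v_min) abort("`v_max` must exceed `v_min`.")
  structure(
    list(v_min = v_min, v_max = v_max, period = period, shape = "sinusoid"),
    class = "pulse_profile"
  )
}

#' @rdname pulse_profile
#' @param pulse A `pulse_profile`.
#' @param t Time(s) in seconds.
#' @return `inlet_velocity()`: inlet mean velocity (m/s) at `t`.
#' @export
inlet_velocity <- function(pulse, t) {
  stopifnot(inherits(pulse, "pulse_profile"))
  mean_v <- (pulse$v_min + pulse$v_max) / 2
  amp <- (pulse$v_max - pulse$v_min) / 2
  mean_v + amp * sin(2 * pi * t / pulse$period)
}

#' Flow-domain geometries
#'
#' Straight rigid-walled geometries for the fully developed laminar
#' solvers: a plane channel of half-height `half_height` (full width
#' `2 * half_height`) or a circular tube of radius `radius`, both of
#' streamwise length `length`. The default channel mirrors the main
#' carotid lumen scale: width 6.3 mm, length 60 mm.
#'
#' @param half_height Channel half-height (m).
#' @param radius Tube radius (m).
#' @param length Streamwise length (m).
#' @return An object of class `flow_geometry`.
#' @export
channel_geometry <- function(half_height = 0.00315, length = 0.06) {
  check_positive(half_height, "half_height")
  check_positive(length, "length")
  structure(list(type = "channel", half_height = half_height,
                 length = length),
            class = "flow_geometry")
}

#' @rdname channel_geometry
#' @export
tube_geometry <- function(radius = 0.00315, length = 0.06) {
  check_positive(radius, "radius")
  check_positive(length, "length")
  structure(list(type = "tube", radius = radius, length = length),
            class = "flow_geometry")
}

# cross-stream extent used for grids and band definitions
geometry_span <- function(geometry) {
  switch(geometry$type,
         channel = geometry$half_height,
         tube = geometry$radius)
}

#' Define a flow problem
#'
#' Bundles geometry, inlet forcing, outlet pressure, fluid properties and
#' discretisation for the incompressible laminar solvers. Walls are rigid
#' and no-slip; gravity is dropped (the single outlet gauge pressure fixes
#' the datum of a horizontal vessel).
#'
#' @param geometry A [channel_geometry()] or [tube_geometry()].
#' @param inlet Either a steady inlet mean velocity (m/s, scalar >= 0) or
#'   a [pulse_profile()].
#' @param outlet_gauge_pressure_pa Outlet static gauge pressure (Pa);
#'   default 13332, the mean of healthy systolic/diastolic pressures.
#' @param rho Blood density (kg/m^3); default 1060.
#' @param rheology A [casson_params()] object.
#' @param nx Streamwise grid intervals (default 256).
#' @param ny Cross-stream grid intervals (default 64).
#' @param dt Time step (s) for pulsatile runs; must satisfy the advective
#'   CFL condition `v_max * dt / dx <= 0.5`. Default 2e-4.
#' @param n_periods Minimum number of pulse periods to integrate
#'   (default 3; the solver can extend the run until periodic).
#' @return An object of class `flow_problem`.
#' @examples
#' prob <- flow_problem(channel_geometry(), inlet = 0.3)
#' @export
flow_problem <- function(geometry = channel_geometry(),
                         inlet = pulse_profile(),
                         outlet_gauge_pressure_pa = 13332,
                         rho = 1060,
                         rheology = casson_params(),
                         nx = 256L, ny = 64L,
                         dt = 2e-4, n_periods = 3L) {
  stopifnot(inherits(geometry, "flow_geometry"),
            inherits(rheology, "casson_params"))
  check_number(outlet_gauge_pressure_pa, "outlet_gauge_pressure_pa", lower = 0)
  check_positive(rho, "rho")
  check_positive(dt, "dt")
  if (!is.numeric(nx) || nx < 2 || !is.numeric(ny) || ny < 4 ||
      ny %% 2 != 0) {
    abort("`nx` must be >= 2 and `ny` an even integer >= 4.")
  }
  if (inherits(inlet, "pulse_profile")) {
    if (n_periods < 2L) {
      abort("`n_periods` must be >= 2 for pulsatile problems.")
    }
  } else {
    check_number(inlet, "inlet", lower = 0)
  }
  structure(
    list(geometry = geometry, inlet = inlet,
         outlet_gauge_pressure_pa = outlet_gauge_pressure_pa,
         rho = rho, rheology = rheology,
         nx = as.integer(nx), ny = as.integer(ny),
         dt = dt, n_periods = as.integer(n_periods)),
    class = "flow_problem"
  )
}

# Advective CFL number at the peak inlet velocity.
cfl_number <- function(problem) {
  v_max <- if (inherits(problem$inlet, "pulse_profile")) {
    problem$inlet$v_max
  } else {
    problem$inlet
  }
  dx <- problem$geometry$length / problem$nx
  v_max * problem$dt / dx
}

check_cfl <- function(problem) {
  cfl <- cfl_number(problem)
  if (cfl > 0.5) {
    abort(sprintf(
      "Advective CFL %.3f exceeds 0.5 at peak velocity; reduce `dt` or `nx`.",
      cfl), class = "oxyshear_cfl_error")
  }
  invisible(cfl)
}
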