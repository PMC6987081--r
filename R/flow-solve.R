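# Fully developed laminar flow of a Casson fluid in straight geometries.
#
# For a rigid straight channel or tube, incompressible laminar flow is
# exactly unidirectional: u = u(y) e_x, v = 0, and continuity is satisfied
# identically. The streamwise momentum equation reduces to
#   rho du/dt = G + d/dy( mu(|du/dy|) du/dy ),   G = -dp/dx,
# (with the cylindrical form in a tube). The solvers below discretise this
# with a conservative second-order finite-volume scheme on cross-stream
# nodes, treat time implicitly (backward Euler), lag the Casson viscosity
# by Picard iteration, and determine G(t) as the Lagrange multiplier that
# enforces the prescribed inlet mean velocity.

# ---- Casson law inversion --------------------------------------------------

#' Shear rate sustaining a given shear stress under the Casson law
#'
#' Inverts the (optionally capped) Casson constitutive law. Below the
#' yield stress the uncapped material does not flow (`gamma_dot = 0`);
#' with a finite viscosity cap the low-stress branch is Newtonian at the
#' cap viscosity, so any positive stress produces slow creep.
#'
#' @param tau Shear stress magnitude(s), Pa, >= 0.
#' @param p A [casson_params()] object.
#' @return Shear rate(s), 1/s.
#' @export
casson_shear_rate_from_stress <- function(tau, p) {
  stopifnot(inherits(p, "casson_params"))
  if (any(tau < 0)) abort("`tau` must be >= 0.")
  d <- casson_derived(p)
  mu_c <- d$mu_high_shear
  tau_y <- d$yield_stress
  if (tau_y == 0) return(tau / mu_c)
  casson_branch <- function(t) ((sqrt(t) - sqrt(tau_y))^2) / mu_c
  if (!is.finite(p$mu_cap)) {
    ifelse(tau > tau_y, casson_branch(pmax(tau, tau_y)), 0)
  } else {
    if (p$mu_cap <= mu_c) {
      abort("`mu_cap` must exceed the infinite-shear viscosity to invert.")
    }
    # shear rate at which the Casson viscosity reaches the cap
    g_cap <- tau_y / (sqrt(p$mu_cap) - sqrt(mu_c))^2
    tau_c <- p$mu_cap * g_cap
    ifelse(tau <= tau_c, tau / p$mu_cap, casson_branch(pmax(tau, tau_y)))
  }
}

#' Semi-analytic Casson-Poiseuille tube profile
#'
#' Exact momentum balance in a straight tube gives the linear stress
#' profile `tau(r) = wall_shear * r / R`. Inverting the Casson law yields
#' the shear rate, and inward integration from the no-slip wall the
#' velocity. With an uncapped law and `wall_shear <= yield_stress` the
#' fluid does not flow; below the yield radius the profile has a solid
#' plug moving at the centreline velocity. Serves as the independent
#' oracle for the numerical solvers.
#'
#' @param wall_shear Wall shear stress (Pa), > 0.
#' @param radius Tube radius (m).
#' @param rheology A [casson_params()] object.
#' @param n_points Number of radial nodes (default 1000).
#' @return A tibble with columns `r_m`, `u_m_s`, `tau_pa`,
#'   `gamma_dot_per_s`, and attributes `flow_rate_m3_s`,
#'   `mean_velocity_m_s`, `plug_radius_m`, `no_flow`.
#' @export
casson_tube_profile <- function(wall_shear, radius, rheology = casson_params(),
                                n_points = 1000L) {
  check_positive(wall_shear, "wall_shear")
  check_positive(radius, "radius")
  stopifnot(inherits(rheology, "casson_params"))
  d <- casson_derived(rheology)
  r <- seq(0, radius, length.out = n_points)
  tau <- wall_shear * r / radius

  no_flow <- !is.finite(rheology$mu_cap) && wall_shear <= d$yield_stress
  if (no_flow) {
    gd <- rep(0, n_points)
    u <- rep(0, n_points)
  } else {
    gd <- casson_shear_rate_from_stress(tau, rheology)
    # u(r) = integral_r^R gamma_dot dr'
    u <- rev(cumtrapz1(r, rev(gd)))
  }
  plug_radius <- if (!is.finite(rheology$mu_cap)) {
    min(radius, radius * d$yield_stress / wall_shear)
  } else {
    0
  }
  out <- tibble(r_m = r, u_m_s = u, tau_pa = tau, gamma_dot_per_s = gd)
  attr(out, "flow_rate_m3_s") <- 2 * pi * trapz1(r, u * r)
  attr(out, "mean_velocity_m_s") <- 2 * trapz1(r, u * r) / radius^2
  attr(out, "plug_radius_m") <- plug_radius
  attr(out, "no_flow") <- no_flow
  out
}

# ---- 1-D cross-stream discretisation --------------------------------------

# Node coordinates across the section: channel spans [-h, h], tube [0, R].
cross_nodes <- function(geometry, ny) {
  span <- geometry_span(geometry)
  if (geometry$type == "channel") {
    seq(-span, span, length.out = ny + 1L)
  } else {
    seq(0, span, length.out = ny + 1L)
  }
}

# Mean (bulk) velocity of a nodal profile, walls included. Composite
# Simpson quadrature (ny is even): exact for the parabolic profile, so
# the Newtonian limit of the solver is exact to rounding.
simpson_weights <- function(n_nodes, delta) {
  w <- rep(c(4, 2), length.out = n_nodes - 2L)
  c(1, w[-length(w)], 4, 1) * delta / 3
}

profile_mean_velocity <- function(u, nodes, geometry) {
  w <- simpson_weights(length(nodes), nodes[2] - nodes[1])
  if (geometry$type == "channel") {
    sum(w * u) / (2 * geometry_span(geometry))
  } else {
    2 * sum(w * u * nodes) / geometry_span(geometry)^2
  }
}

# Face gradients (u[i+1] - u[i]) / delta, i = 1..ny.
face_gradients <- function(u, delta) diff(u) / delta

# Tridiagonal coefficients of the diffusion operator L on the unknown
# nodes (interior for channel; centreline..last interior for tube).
# Returns list(a, b, c) with a = sub-, b = main, c = super-diagonal.
build_L <- function(mu_face, delta, geometry, ny) {
  if (geometry$type == "channel") {
    m <- ny - 1L                       # unknowns at nodes 2..ny
    i <- seq_len(m) + 1L
    a <- mu_face[i - 1L] / delta^2
    c <- mu_face[i] / delta^2
    b <- -(mu_face[i] + mu_face[i - 1L]) / delta^2
    a[1L] <- 0; c[m] <- 0
    list(a = a, b = b, c = c)
  } else {
    m <- ny                            # unknowns at nodes 1..ny (r = 0 in)
    a <- numeric(m); b <- numeric(m); c <- numeric(m)
    b[1L] <- -4 * mu_face[1L] / delta^2
    c[1L] <- 4 * mu_face[1L] / delta^2
    if (m > 1L) {
      k <- 2:m
      r_k <- (k - 1) * delta
      rf_hi <- (k - 0.5) * delta
      rf_lo <- (k - 1.5) * delta
      a[k] <- rf_lo * mu_face[k - 1L] / (r_k * delta^2)
      c[k] <- rf_hi * mu_face[k] / (r_k * delta^2)
      b[k] <- -(rf_hi * mu_face[k] + rf_lo * mu_face[k - 1L]) / (r_k * delta^2)
      c[m] <- 0                        # wall neighbour is zero
    }
    list(a = a, b = b, c = c)
  }
}

# Apply L (with full boundary handling) to a full nodal profile.
apply_L <- function(u, mu_face, delta, geometry, ny) {
  L <- build_L(mu_face, delta, geometry, ny)
  w <- unknown_values(u, geometry, ny)
  m <- length(w)
  res <- L$b * w
  if (m > 1L) {
    res[-m] <- res[-m] + L$c[-m] * w[-1L]
    res[-1L] <- res[-1L] + L$a[-1L] * w[-m]
  }
  res
}

unknown_values <- function(u, geometry, ny) {
  if (geometry$type == "channel") u[2:ny] else u[1:ny]
}

full_profile <- function(w, geometry, ny) {
  if (geometry$type == "channel") c(0, w, 0) else c(w, 0)
}

# Solve (alpha I - L) w = rhs for the unknown nodes; alpha may be 0
# (steady) or rho/dt (implicit time step).
solve_linear <- function(L, alpha, rhs) {
  solve_tridiag(-L$a, alpha - L$b, -L$c, rhs)
}

# Nodal shear rate |du/dy| with one-sided second-order wall stencils.
nodal_shear_rate <- function(u, delta) {
  n <- length(u)
  g <- numeric(n)
  g[1] <- (-3 * u[1] + 4 * u[2] - u[3]) / (2 * delta)
  g[n] <- (3 * u[n] - 4 * u[n - 1] + u[n - 2]) / (2 * delta)
  g[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / (2 * delta)
  abs(g)
}

# ---- steady solver ---------------------------------------------------------

# Picard iteration for the steady profile at prescribed mean velocity U.
solve_profile_steady <- function(problem, U, relax = 0.7, tol = 1e-11,
                                 maxit = 400L) {
  geometry <- problem$geometry
  ny <- problem$ny
  nodes <- cross_nodes(geometry, ny)
  delta <- nodes[2] - nodes[1]
  n <- ny + 1L

  if (U == 0) {
    return(list(u = rep(0, n), G = 0, nodes = nodes,
                iterations = 0L, residual = 0))
  }
  # initial viscosity from a Newtonian-scale shear-rate guess
  mu_face <- apparent_viscosity(rep(3 * U / geometry_span(geometry), ny),
                                problem$rheology)
  u <- rep(0, n)
  for (it in seq_len(maxit)) {
    L <- build_L(mu_face, delta, geometry, ny)
    w_unit <- solve_linear(L, 0, rep(1, length(L$b)))
    u_unit <- full_profile(w_unit, geometry, ny)
    mv_unit <- profile_mean_velocity(u_unit, nodes, geometry)
    G <- U / mv_unit
    u_new <- G * u_unit
    du <- max(abs(u_new - u)) / max(abs(u_new))
    u <- u_new
    mu_new <- apparent_viscosity(abs(face_gradients(u, delta)),
                                 problem$rheology)
    dmu <- max(abs(mu_new - mu_face) / mu_face)
    mu_face <- relax * mu_new + (1 - relax) * mu_face
    if (du < tol && dmu < 1e-9) break
  }
  if (it == maxit && (du >= tol || dmu >= 1e-9)) {
    abort(sprintf(
      "Steady Picard iteration failed to converge (du=%.2e, dmu=%.2e).",
      du, dmu), class = "oxyshear_solver_error")
  }
  # residual with viscosity consistent with the converged profile
  mu_cons <- apparent_viscosity(abs(face_gradients(u, delta)),
                                problem$rheology)
  res <- apply_L(u, mu_cons, delta, geometry, ny) + G
  list(u = u, G = G, nodes = nodes, iterations = it,
       residual = max(abs(res)) / abs(G))
}

# Assemble a flow_field from a cross-stream profile and pressure gradient.
make_flow_field <- function(problem, u_prof, G, time = 0) {
  geometry <- problem$geometry
  nx <- problem$nx
  ny <- problem$ny
  nodes <- cross_nodes(geometry, ny)
  delta <- nodes[2] - nodes[1]
  x <- seq(0, geometry$length, length.out = nx + 1L)
  ones_x <- rep(1, nx + 1L)

  gd <- if (all(u_prof == 0)) rep(0, ny + 1L) else nodal_shear_rate(u_prof, delta)
  mu <- apparent_viscosity(gd, problem$rheology)
  tau <- mu * gd
  p_line <- problem$outlet_gauge_pressure_pa + G * (geometry$length - x)

  structure(
    list(
      time = time,
      x = x, y = nodes,
      u = outer(u_prof, ones_x),
      v = matrix(0, ny + 1L, nx + 1L),
      p = outer(rep(1, ny + 1L), p_line),
      gamma_dot = outer(gd, ones_x),
      mu = outer(mu, ones_x),
      tau = outer(tau, ones_x),
      mask = matrix(TRUE, ny + 1L, nx + 1L),
      geometry = geometry,
      rheology = problem$rheology,
      meta = list(dpdx = -G, mean_velocity = profile_mean_velocity(
        u_prof, nodes, geometry))
    ),
    class = "flow_field"
  )
}

#' Steady fully developed flow
#'
#' Solves the steady cross-stream momentum balance of a Casson fluid in a
#' channel or tube at the prescribed inlet mean velocity, by Picard
#' (fixed-point) iteration on the viscosity with the pressure gradient as
#' the Lagrange multiplier of the flow-rate constraint. At convergence the
#' viscosity field is consistent with the shear-rate field through the
#' Casson law and the relative momentum residual is below 1e-6.
#'
#' @param problem A [flow_problem()] with a steady (scalar) inlet.
#' @return A `flow_field`: nodal `u`, `v`, `p`, `gamma_dot`, `mu`, `tau`
#'   matrices (rows = cross-stream nodes, columns = streamwise nodes)
#'   plus grid coordinates and solver diagnostics in `$meta`.
#' @examples
#' prob <- flow_problem(channel_geometry(), inlet = 0.3, nx = 16, ny = 32)
#' field <- solve_steady(prob)
#' field$meta$residual
#' @export
solve_steady <- function(problem) {
  stopifnot(inherits(problem, "flow_problem"))
  if (inherits(problem$inlet, "pulse_profile")) {
    abort("Problem has a pulsatile inlet; use solve_pulsatile().")
  }
  sol <- solve_profile_steady(problem, problem$inlet)
  field <- make_flow_field(problem, sol$u, sol$G, time = 0)
  field$meta$residual <- sol$residual
  field$meta$iterations <- sol$iterations
  field
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field>", x$geometry$type,
      sprintf("t = %g s, %d x %d nodes\n", x$time, nrow(x$u), ncol(x$u)))
  cat(sprintf("  mean velocity %.4g m/s, dp/dx %.4g Pa/m\n",
              x$meta$mean_velocity, x$meta$dpdx))
  cat(sprintf("  max |u| %.4g m/s, wall tau %.4g Pa\n",
              max(abs(x$u)), max(x$tau)))
  invisible(x)
}

#' Tidy a flow field into a long tibble
#'
#' @param x A `flow_field`.
#' @param ... Unused.
#' @return Tibble with one row per grid node: `x_m`, `y_m`, `u_m_s`,
#'   `v_m_s`, `p_pa`, `gamma_dot_per_s`, `mu_pa_s`, `tau_pa`, `time_s`.
#' @method tidy flow_field
#' @export
tidy.flow_field <- function(x, ...) {
  grid <- expand.grid(y_m = x$y, x_m = x$x, KEEP.OUT.ATTRS = FALSE)
  tibble(
    x_m = grid$x_m, y_m = grid$y_m,
    u_m_s = as.vector(x$u), v_m_s = as.vector(x$v),
    p_pa = as.vector(x$p),
    gamma_dot_per_s = as.vector(x$gamma_dot),
    mu_pa_s = as.vector(x$mu), tau_pa = as.vector(x$tau),
    time_s = x$time
  )
}

#' Maximum discrete velocity divergence of a field
#'
#' Central-difference du/dx + dv/dy over interior nodes; the fully
#' developed solutions are divergence-free to rounding.
#'
#' @param field A `flow_field`.
#' @return Maximum absolute discrete divergence (1/s).
#' @export
divergence <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  nxp <- length(field$x); nyp <- length(field$y)
  dx <- field$x[2] - field$x[1]; dy <- field$y[2] - field$y[1]
  dudx <- (field$u[, 3:nxp] - field$u[, 1:(nxp - 2)]) / (2 * dx)
  dvdy <- (field$v[3:nyp, ] - field$v[1:(nyp - 2), ]) / (2 * dy)
  max(abs(dudx[2:(nyp - 1), ]) + abs(dvdy[, 2:(nxp - 1)]))
}

# ---- pulsatile solver ------------------------------------------------------

#' Pulsatile fully developed flow
#'
#' Integrates the unsteady cross-stream momentum equation with an
#' implicit (backward Euler) step, Picard sub-iterations on the Casson
#' viscosity, and a time-varying pressure gradient enforcing the
#' sinusoidal inlet mean velocity. Starts from the steady solution at the
#' phase-zero velocity and runs at least `n_periods` periods, extending
#' (up to `max_periods`) until successive periods agree to
#' `periodic_tol * v_max` in the velocity profile.
#'
#' @param problem A [flow_problem()] with a [pulse_profile()] inlet.
#' @param store_phases Number of equally spaced phases of the final
#'   period to return (default 20).
#' @param periodic_tol Relative periodicity tolerance (default 1e-3).
#' @param extend_until_periodic Extend the run past `n_periods` until the
#'   periodicity criterion is met (default TRUE).
#' @param max_periods Hard cap on periods integrated (default 60).
#' @param picard_iter Viscosity sub-iterations per time step (default 2).
#' @return A `flow_series`: list with `fields` (one `flow_field` per
#'   stored phase), `times`, and `meta` (periodicity metric, periods run,
#'   achieved inlet mean).
#' @export
solve_pulsatile <- function(problem, store_phases = 20L,
                            periodic_tol = 1e-3,
                            extend_until_periodic = TRUE,
                            max_periods = 60L, picard_iter = 2L) {
  stopifnot(inherits(problem, "flow_problem"))
  pulse <- problem$inlet
  if (!inherits(pulse, "pulse_profile")) {
    abort("Problem has a steady inlet; use solve_steady().")
  }
  check_cfl(problem)

  geometry <- problem$geometry
  ny <- problem$ny
  nodes <- cross_nodes(geometry, ny)
  delta <- nodes[2] - nodes[1]
  period <- pulse$period
  spp <- store_phases * ceiling(period / (store_phases * problem$dt))
  dt <- period / spp
  stride <- spp %/% store_phases
  alpha <- problem$rho / dt

  init <- solve_profile_steady(problem, inlet_velocity(pulse, 0))
  u <- init$u
  mu_face <- apparent_viscosity(abs(face_gradients(u, delta)),
                                problem$rheology)

  snaps <- matrix(NA_real_, store_phases, ny + 1L)
  snap_G <- numeric(store_phases)
  snap_t <- numeric(store_phases)
  prev_snaps <- NULL
  metric <- Inf
  p_idx <- 0L

  repeat {
    p_idx <- p_idx + 1L
    k <- 0L
    for (s in seq_len(spp)) {
      t_new <- (p_idx - 1L) * period + s * dt
      U_t <- inlet_velocity(pulse, t_new)
      rhs_a_base <- alpha * unknown_values(u, geometry, ny)
      for (pic in seq_len(picard_iter)) {
        L <- build_L(mu_face, delta, geometry, ny)
        w_a <- solve_linear(L, alpha, rhs_a_base)
        w_b <- solve_linear(L, alpha, rep(1, length(L$b)))
        u_a <- full_profile(w_a, geometry, ny)
        u_b <- full_profile(w_b, geometry, ny)
        G <- (U_t - profile_mean_velocity(u_a, nodes, geometry)) /
          profile_mean_velocity(u_b, nodes, geometry)
        u_new <- u_a + G * u_b
        mu_face <- apparent_viscosity(abs(face_gradients(u_new, delta)),
                                      problem$rheology)
      }
      u <- u_new
      if (s %% stride == 0L) {
        k <- k + 1L
        snaps[k, ] <- u
        snap_G[k] <- G
        snap_t[k] <- t_new
      }
    }
    if (!is.null(prev_snaps)) {
      metric <- max(abs(snaps - prev_snaps)) / pulse$v_max
    }
    done <- p_idx >= problem$n_periods &&
      (!extend_until_periodic || metric < periodic_tol ||
         p_idx >= max_periods)
    if (done) break
    prev_snaps <- snaps
  }
  if (metric >= periodic_tol) {
    warn(sprintf(
      "Pulsatile run not periodic to tolerance after %d periods (%.2e).",
      p_idx, metric), class = "oxyshear_periodicity_warning")
  }

  fields <- purrr::map(seq_len(store_phases), function(k) {
    make_flow_field(problem, snaps[k, ], snap_G[k], time = snap_t[k])
  })
  structure(
    list(
      fields = fields,
      times = snap_t,
      problem = problem,
      meta = list(
        periodicity = metric,
        periods_run = p_idx,
        dt = dt,
        steps_per_period = spp,
        inlet_mean_target = (pulse$v_min + pulse$v_max) / 2,
        inlet_mean_achieved = mean(inlet_velocity(
          pulse, (p_idx - 1L) * period + seq_len(spp) * dt))
      )
    ),
    class = "flow_series"
  )
}

#' @export
print.flow_series <- function(x, ...) {
  cat("<flow_series>", length(x$fields), "stored phases,",
      x$meta$periods_run, "periods integrated\n")
  cat(sprintf("  periodicity %.3e (rel. v_max), dt = %.3g s\n",
              x$meta$periodicity, x$meta$dt))
  invisible(x)
}

# ---- wall shear stress -----------------------------------------------------

#' Wall shear stress profile
#'
#' Extracts WSS = mu_wall * |du/dn| at the wall from one-sided
#' second-order differences of the streamwise velocity, with the wall
#' viscosity evaluated from the wall shear rate through the Casson law.
#'
#' @param x A `flow_field` or `flow_series`.
#' @param ... Unused.
#' @return A tibble of class `wss_profile` with columns `x_m` (arc-length
#'   position along the wall), `wall` ("lower"/"upper" for channels,
#'   "wall" for tubes), `wss_pa` and `time_s`.
#' @export
wall_shear_stress <- function(x, ...) UseMethod("wall_shear_stress")

#' @export
wall_shear_stress.flow_field <- function(x, ...) {
  u <- x$u[, 1]                      # profile uniform along the length
  n <- length(u)
  delta <- x$y[2] - x$y[1]
  g_lo <- abs((-3 * u[1] + 4 * u[2] - u[3]) / (2 * delta))
  g_hi <- abs((3 * u[n] - 4 * u[n - 1] + u[n - 2]) / (2 * delta))
  wss_of <- function(g) {
    if (g == 0) 0 else apparent_viscosity(g, x$rheology) * g
  }
  walls <- if (x$geometry$type == "channel") {
    tibble(wall = c("lower", "upper"), wss = c(wss_of(g_lo), wss_of(g_hi)))
  } else {
    tibble(wall = "wall", wss = wss_of(g_hi))
  }
  out <- tidyr::crossing(tibble(x_m = x$x), walls) |>
    dplyr::mutate(wss_pa = .data$wss, time_s = x$time) |>
    dplyr::select("x_m", "wall", "wss_pa", "time_s")
  class(out) <- c("wss_profile", class(out))
  out
}

#' @export
wall_shear_stress.flow_series <- function(x, ...) {
  out <- purrr::list_rbind(purrr::map(x$fields, wall_shear_stress))
  class(out) <- c("wss_profile", class(out))
  out
}

#' @rdname wall_shear_stress
#' @param object A `wss_profile`.
#' @method autoplot wss_profile
#' @export
autoplot.wss_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time_s, .data$wss_pa,
                               colour = .data$wall)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Wall shear stress (Pa)",
                  title = "Wall shear stress over the pulse")
}
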