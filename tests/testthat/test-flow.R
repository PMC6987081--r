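# Solver validation against closed forms and the semi-analytic tube oracle.

test_that("tube oracle reduces to the parabolic profile for Newtonian fluid", {
  mu <- 3e-3; R <- 0.003; tw <- 2
  prof <- casson_tube_profile(tw, R, newtonian_params(mu), n_points = 1000)
  u_exact <- tw * (R^2 - prof$r_m^2) / (2 * R * mu)
  expect_lt(max(abs(prof$u_m_s - u_exact)) / max(u_exact), 1e-3)
  # Poiseuille bulk velocity: tau_w R / (4 mu)
  expect_equal(attr(prof, "mean_velocity_m_s"), tw * R / (4 * mu),
               tolerance = 1e-4)
})

test_that("no flow at or below the yield stress, plug at the core above it", {
  p <- casson_params(mu_cap = Inf)            # yield stress 0.0625 Pa
  ys <- casson_derived(p)$yield_stress
  prof <- casson_tube_profile(ys, 0.003, p)
  expect_true(attr(prof, "no_flow"))
  expect_true(all(prof$u_m_s == 0))

  prof2 <- casson_tube_profile(4 * ys, 0.003, p, n_points = 4001)
  plug <- prof2$r_m < attr(prof2, "plug_radius_m")
  expect_gt(sum(plug), 10)
  expect_true(all(prof2$gamma_dot_per_s[plug] == 0))
  u_plug <- prof2$u_m_s[plug]
  expect_lt(diff(range(u_plug)) / max(prof2$u_m_s), 1e-12)
  expect_equal(max(prof2$u_m_s), u_plug[1])
})

test_that("oracle flow rate agrees with an independent integral identity", {
  # integrating u(r) by parts with u(R) = 0: Q = pi * int gamma_dot r^2 dr
  p <- casson_params(hct = 0.4, preset = "calibrated")
  R <- 0.00315
  prof <- casson_tube_profile(2, R, p, n_points = 1000)
  r_fine <- seq(0, R, length.out = 2e5)
  gd_fine <- casson_shear_rate_from_stress(2 * r_fine / R, p)
  q_indep <- pi * sum(diff(r_fine) *
                        (head(gd_fine * r_fine^2, -1) +
                           tail(gd_fine * r_fine^2, -1)) / 2)
  expect_rel_equal(attr(prof, "flow_rate_m3_s"), q_indep, 0.005)
})

test_that("steady Newtonian channel reproduces plane Poiseuille", {
  mu <- 3e-3; v <- 0.3; h <- 0.00315
  prob <- flow_problem(channel_geometry(h, 0.06), inlet = v,
                       rheology = newtonian_params(mu), nx = 8, ny = 64)
  f <- solve_steady(prob)
  expect_rel_equal(max(f$u) / f$meta$mean_velocity, 1.5, 0.01)
  expect_lt(f$meta$residual, 1e-6)
  expect_lt(divergence(f), 1e-12)
  # pressure decreases monotonically downstream
  expect_true(all(diff(f$p[1, ]) < 0))
  wss <- wall_shear_stress(f)
  expect_rel_equal(unique(wss$wss_pa), 3 * mu * v / h, 0.01)
})

test_that("with a uniform forced viscosity the solver is exactly Newtonian", {
  p <- uniform_viscosity_params()
  h <- 0.00315
  prob <- flow_problem(channel_geometry(h, 0.06), inlet = 0.3,
                       rheology = p, nx = 4, ny = 32)
  f <- solve_steady(prob)
  # parabola is in the exact solution space of the second-order scheme
  u_exact <- 1.5 * 0.3 * (1 - (f$y / h)^2)
  expect_lt(max(abs(f$u[, 1] - u_exact)), 1e-10)
})

test_that("zero inlet velocity yields a quiescent field at outlet pressure", {
  prob <- flow_problem(channel_geometry(), inlet = 0, nx = 4, ny = 16)
  f <- solve_steady(prob)
  expect_true(all(f$u == 0))
  expect_true(all(f$p == prob$outlet_gauge_pressure_pa))
  expect_true(all(wall_shear_stress(f)$wss_pa == 0))
})

tube_oracle_l2_error <- function(ny, rheology = casson_params(preset = "calibrated")) {
  R <- 0.00315
  prob <- flow_problem(tube_geometry(R, 0.06), inlet = 0.3,
                       rheology = rheology, nx = 4, ny = ny)
  f <- solve_steady(prob)
  tau_wall <- -f$meta$dpdx * R / 2
  oracle <- casson_tube_profile(tau_wall, R, rheology, n_points = 40001)
  u_o <- approx(oracle$r_m, oracle$u_m_s, xout = f$y)$y
  list(l2 = sqrt(mean((f$u[, 1] - u_o)^2)) / sqrt(mean(u_o^2)),
       field = f, tau_wall = tau_wall)
}

test_that("steady Casson tube matches the semi-analytic oracle", {
  res <- tube_oracle_l2_error(128)
  expect_lt(res$l2, 0.01)
  # wall shear stress consistent with the imposed pressure gradient
  wss <- wall_shear_stress(res$field)
  expect_rel_equal(unique(wss$wss_pa), res$tau_wall, 0.005)
})

test_that("halving the grid spacing shrinks the error about 4-fold", {
  e32 <- tube_oracle_l2_error(32)$l2
  e64 <- tube_oracle_l2_error(64)$l2
  expect_gt(e32 / e64, 3)
})

test_that("the inlet pulse is periodic and CFL violations are rejected", {
  pulse <- pulse_profile()
  expect_equal(inlet_velocity(pulse, 0), inlet_velocity(pulse, pulse$period))
  expect_equal(inlet_velocity(pulse, pulse$period / 4), pulse$v_max)
  bad <- flow_problem(channel_geometry(), inlet = pulse_profile(),
                      nx = 256, ny = 16, dt = 0.01)
  expect_error(solve_pulsatile(bad), class = "oxyshear_cfl_error")
})

test_that("slow pulsatile Newtonian flow is quasi-steady plane Poiseuille", {
  mu <- 3e-3; h <- 0.00315
  pulse <- pulse_profile(v_min = 0.05, v_max = 0.15, period = 50)
  prob <- flow_problem(channel_geometry(h, 0.06), inlet = pulse,
                       rheology = newtonian_params(mu),
                       nx = 8, ny = 32, dt = 0.02, n_periods = 2)
  sol <- solve_pulsatile(prob)
  expect_lt(sol$meta$periodicity, 1e-3)
  expect_rel_equal(sol$meta$inlet_mean_achieved, 0.1, 0.005)

  for (f in sol$fields) {
    U_t <- inlet_velocity(pulse, f$time)
    u_qs <- 1.5 * U_t * (1 - (f$y / h)^2)
    expect_lt(max(abs(f$u[, 1] - u_qs)) / max(u_qs), 0.02)
    # mass conservation: identical flux through every cross-section
    nodes <- f$y
    flux <- apply(f$u, 2, function(col) {
      sum(diff(nodes) * (head(col, -1) + tail(col, -1)) / 2)
    })
    expect_lt(max(abs(flux - flux[1])) / abs(flux[1]), 0.005)
  }

  # phase-averaged WSS is bracketed by the steady extremes
  wss <- wall_shear_stress(sol)
  wss_mean <- mean(wss$wss_pa)
  steady_at <- function(v) {
    fp <- flow_problem(channel_geometry(h, 0.06), inlet = v,
                       rheology = newtonian_params(mu), nx = 8, ny = 32)
    mean(wall_shear_stress(solve_steady(fp))$wss_pa)
  }
  expect_gt(wss_mean, steady_at(pulse$v_min))
  expect_lt(wss_mean, steady_at(pulse$v_max))
})
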