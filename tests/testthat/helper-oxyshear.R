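# Fixtures built in code: canonical curves, Newtonian rheology stubs.

# One curve following the hyperbola EI(SS) = ei_max * SS / (ss_half + SS).
make_hyperbola_curve <- function(ei_max = 0.6, ss_half = 2,
                                 ss = ss_levels_pa,
                                 condition = "oxygenated",
                                 phase = "before_5Pa",
                                 subject = "S1", replicate = 1L) {
  tibble::tibble(
    shear_stress_pa = ss,
    ei = ei_max * ss / (ss_half + ss),
    condition = condition, phase = phase,
    subject = subject, replicate = replicate
  )
}

# Curve sampled exactly from a calibration preset.
make_preset_curve <- function(name = "eq1_oxygenated", ss = ss_levels_pa,
                              subject = "S1", phase = "before_5Pa",
                              replicate = 1L) {
  cal <- cal_preset(name)
  tibble::tibble(
    shear_stress_pa = ss, ei = predict(cal, ss),
    condition = cal$condition, phase = phase,
    subject = subject, replicate = replicate
  )
}

# Effectively Newtonian Casson parameters: vanishing hematocrit makes the
# yield stress negligible and the viscosity constant at ~mu.
newtonian_params <- function(mu = 3e-3) {
  casson_params(hct = 1e-9, mu0 = mu, mu_fallback = mu, mu_cap = Inf)
}

# Casson parameters whose cap equals the infinite-shear viscosity, forcing
# a uniform viscosity field (exact Newtonian limit of the solver).
uniform_viscosity_params <- function(hct = 0.4, mu0 = 1.45e-3) {
  mu_c <- mu0 * (1 - hct)^(-0.5)
  casson_params(hct = hct, mu0 = mu0, mu_fallback = mu_c, mu_cap = mu_c)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), tol)
}
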