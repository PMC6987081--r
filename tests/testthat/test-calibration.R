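test_that("preset evaluation matches direct arithmetic on the coefficients", {
  cal <- cal_preset("eq1_oxygenated")
  # independent elementwise evaluation of the printed coefficients
  direct <- function(ss) 0.5464 * exp(0.00356 * ss) - 0.5224 * exp(-0.5395 * ss)
  ss <- c(0, 0.3, 2.91, 5.15, 50)
  expect_equal(predict(cal, ss), direct(ss), tolerance = 1e-14)
  expect_equal(predict(cal, 0), 0.0240, tolerance = 1e-12)
  expect_equal(predict(cal, 2.91), 0.4434011, tolerance = 1e-6)
  expect_equal(predict(cal, 5.15), 0.5240501, tolerance = 1e-6)
  expect_equal(predict(cal_preset("eq2_deoxygenated"), 0), 0.0477,
               tolerance = 1e-12)
  expect_error(predict(cal, -1), class = "oxyshear_domain_error")
})

test_that("presets are strictly increasing and ordered deoxy > oxy", {
  oxy <- cal_preset("eq1_oxygenated")
  deoxy <- cal_preset("eq2_deoxygenated")
  expect_true(oxy$monotone)
  expect_true(deoxy$monotone)
  ss <- seq(0.3, 50, length.out = 1e4)
  ei_o <- predict(oxy, ss)
  ei_d <- predict(deoxy, ss)
  expect_true(all(diff(ei_o) > 0))
  expect_true(all(diff(ei_d) > 0))
  expect_true(all(ei_d > ei_o))
})

test_that("inversion is the exact inverse on the attainable range", {
  cal <- cal_preset("eq1_oxygenated")
  expect_equal(ei_invert(cal, 0.0240), 0, tolerance = 1e-10)
  expect_equal(ei_invert(cal, predict(cal, 7.7)), 7.7, tolerance = 1e-8)
  ei_grid <- predict(cal, seq(0, 80, length.out = 40))
  back <- predict(cal, ei_invert(cal, ei_grid))
  expect_lt(max(abs(back - ei_grid)), 1e-10)
  # the stagnation-region elongation lies between the 2.91 and 5.15 Pa levels
  expect_gt(ei_invert(cal, 0.480), 2.91)
  expect_lt(ei_invert(cal, 0.480), 5.15)
  expect_error(ei_invert(cal, 0.9), class = "oxyshear_range_error")
  expect_error(ei_invert(cal, 0.001), class = "oxyshear_range_error")
})

test_that("noiseless model data is refit to the generating coefficients", {
  for (name in c("eq1_oxygenated", "eq2_deoxygenated")) {
    cal <- cal_preset(name)
    d <- tibble::tibble(shear_stress_pa = ss_levels_pa,
                        ei = predict(cal, ss_levels_pa))
    truth <- c(cal$c1, cal$r1, cal$c2, cal$r2)
    for (seed in c(1L, 99L)) {
      fit <- fit_ei_calibration(d, condition = cal$condition, seed = seed)
      est <- c(fit$c1, fit$r1, fit$c2, fit$r2)
      expect_lt(max(abs(est - truth) / truth), 1e-4)
      expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    }
  }
})

test_that("coefficients are recovered from noisy curves (Monte-Carlo)", {
  cal <- cal_preset("eq1_oxygenated")
  truth <- c(cal$c1, cal$r1, cal$c2, cal$r2)
  d0 <- tibble::tibble(shear_stress_pa = ss_levels_pa,
                       ei = predict(cal, ss_levels_pa))
  errs <- vapply(1:30, function(s) {
    d <- d0
    d$ei <- d$ei + withr::with_seed(s, rnorm(nrow(d), 0, 0.005))
    f <- fit_ei_calibration(d, condition = "oxygenated", seed = s)
    abs(c(f$c1, f$r1, f$c2, f$r2) - truth)
  }, numeric(4))
  expect_lt(max(apply(errs, 1, median)), 0.02)
})

test_that("R-squared follows its definition and flags degenerate input", {
  cal <- cal_preset("eq1_oxygenated")
  d <- tibble::tibble(shear_stress_pa = ss_levels_pa,
                      ei = predict(cal, ss_levels_pa))
  expect_equal(calibration_r_squared(cal, d), 1)
  # manual recomputation on perturbed data
  d$ei <- d$ei + withr::with_seed(5, rnorm(10, 0, 0.02))
  res <- d$ei - predict(cal, d$shear_stress_pa)
  manual <- 1 - sum(res^2) / sum((d$ei - mean(d$ei))^2)
  expect_equal(calibration_r_squared(cal, d), manual)
  expect_lt(calibration_r_squared(cal, d), 1)
  flat <- tibble::tibble(shear_stress_pa = c(1, 2, 3), ei = c(0.3, 0.3, 0.3))
  expect_error(calibration_r_squared(cal, flat),
               class = "oxyshear_undefined_r2")
})

test_that("fit preconditions are enforced", {
  d <- tibble::tibble(shear_stress_pa = c(1, 2, 3, 4), ei = c(.1, .2, .3, .4))
  expect_error(fit_ei_calibration(d), class = "oxyshear_insufficient_data")
})

test_that("ghost curves are poorly described by the monotone model family", {
  # the two-term exponential family is increasing wherever c1, c2 > 0 and
  # r1 >= 0, so a fragmenting (falling) ghost curve cannot be represented:
  # the best fit has a large residual
  ghosts <- generate_ghost_curves(synth_config(n_subjects = 1, seed = 4))
  curve <- dplyr::filter(ghosts, replicate == 1)
  fit <- fit_ei_calibration(
    dplyr::select(curve, shear_stress_pa, ei), condition = "oxygenated")
  expect_true(fit$monotone)         # family is intrinsically monotone
  expect_lt(fit$r_squared, 0.5)     # and therefore cannot track the fall
})

test_that("tidiers return the documented shapes", {
  cal <- cal_preset("eq1_oxygenated")
  td <- tidy(cal)
  expect_equal(td$term, c("c1", "r1", "c2", "r2"))
  expect_equal(td$estimate, c(0.5464, 0.00356, 0.5224, 0.5395))
  gl <- glance(cal)
  expect_equal(gl$r_squared, 0.9952)
  expect_equal(gl$ei_at_zero, 0.0240, tolerance = 1e-12)
})
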