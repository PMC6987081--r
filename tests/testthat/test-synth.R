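test_that("degenerate generator reproduces the preset curves exactly", {
  cfg <- synth_config(noise_sd = 0, subject_sd = 0, after_ss_effect = 0,
                      n_subjects = 2, seed = 5)
  curves <- generate_dataset(cfg)
  expect_equal(nrow(curves), 2 * 2 * 2 * 2 * 10)
  oxy <- dplyr::filter(curves, condition == "oxygenated")
  expect_equal(oxy$ei,
               predict(cal_preset("eq1_oxygenated"), oxy$shear_stress_pa))
  deoxy <- dplyr::filter(curves, condition == "deoxygenated")
  expect_equal(deoxy$ei,
               predict(cal_preset("eq2_deoxygenated"), deoxy$shear_stress_pa))
})

test_that("generation is bit-reproducible from the seed", {
  a <- generate_dataset(synth_config(seed = 42))
  b <- generate_dataset(synth_config(seed = 42))
  expect_identical(a, b)
  expect_false(identical(a, generate_dataset(synth_config(seed = 43))))
  expect_equal(nrow(curve_keys <- dplyr::distinct(
    a, subject, condition, phase, replicate)), 80)
})

test_that("conditioning raises EI only at the low-stress levels", {
  cfg <- synth_config(noise_sd = 0, subject_sd = 0, after_ss_effect = 0.01,
                      n_subjects = 1, n_replicates = 1, seed = 1)
  curves <- generate_dataset(cfg)
  wide <- tidyr::pivot_wider(curves, names_from = phase, values_from = ei)
  shift <- wide$after_5Pa - wide$before_5Pa
  expect_equal(shift[wide$shear_stress_pa <= 1.65],
               rep(0.01, sum(wide$shear_stress_pa <= 1.65)))
  expect_equal(shift[wide$shear_stress_pa > 1.65],
               rep(0, sum(wide$shear_stress_pa > 1.65)))
})

test_that("deoxygenated mean EI exceeds oxygenated at every level", {
  for (seed in 1:3) {
    sm <- summarize_protocol(generate_dataset(synth_config(seed = seed)))
    wide <- tidyr::pivot_wider(sm[, c("condition", "phase",
                                      "shear_stress_pa", "mean_ei")],
                               names_from = condition,
                               values_from = mean_ei)
    expect_true(all(wide$deoxygenated > wide$oxygenated))
  }
})

test_that("effects pushing mean EI outside (0,1) are rejected", {
  expect_error(synth_config(after_ss_effect = 0.7),
               class = "oxyshear_config_error")
  expect_error(synth_config(after_ss_effect = -0.11),
               class = "oxyshear_config_error")
})

test_that("ghost curves fragment: negative EI at high shear stress", {
  ghosts <- generate_ghost_curves(synth_config(seed = 9))
  at50 <- dplyr::filter(ghosts, shear_stress_pa == 50)
  expect_true(all(at50$ei < 0))
  # rises to ~0.3 by 2.91 Pa
  at291 <- dplyr::filter(ghosts, shear_stress_pa == 2.91)
  expect_true(all(abs(at291$ei - 0.3) < 0.1))
  # exclusion path: the Lineweaver-Burke fit drops the non-positive points
  one <- dplyr::filter(ghosts, subject == "G01", replicate == 1)
  expect_warning(fit <- lb_fit(one), class = "oxyshear_exclusion_warning")
  expect_gt(fit$n_excluded, 0)
  expect_lt(fit$n_used, 10)
})

test_that("the calibration round trip recovers the truth curves", {
  ok <- 0L
  n_seeds <- 10L
  grid <- seq(0.3, 50, length.out = 200)
  for (seed in seq_len(n_seeds)) {
    sm <- summarize_protocol(generate_dataset(synth_config(seed = seed)))
    worst <- 0
    for (cond in c("oxygenated", "deoxygenated")) {
      mean_curve <- sm |>
        dplyr::filter(condition == cond, phase == "before_5Pa") |>
        dplyr::rename(ei = mean_ei)
      fit <- fit_ei_calibration(mean_curve, condition = cond, seed = seed)
      truth <- cal_preset(cond)
      worst <- max(worst, max(abs(predict(fit, grid) - predict(truth, grid))))
    }
    if (worst < 0.01) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.95 * n_seeds))
})
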