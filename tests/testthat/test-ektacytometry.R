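test_that("elongation index matches its definition and is antisymmetric", {
  expect_identical(elongation_index(2, 2), 0)
  expect_identical(elongation_index(3, 1), 0.5)
  expect_identical(elongation_index(1, 3), -0.5)

  set.seed(11)
  for (k in 1:50) {
    a <- runif(1, 0.1, 10)
    b <- runif(1, 0.1, 10)
    expect_equal(elongation_index(a, b), -elongation_index(b, a))
    expect_true((elongation_index(a, b) == 0) == (a == b))
    expect_true(abs(elongation_index(a, b)) < 1)
  }

  expect_error(elongation_index(0, 1), class = "oxyshear_invalid_measurement")
  expect_error(elongation_index(1, -2), class = "oxyshear_invalid_measurement")
})

test_that("Lineweaver-Burke fit is exact on noiseless hyperbolas", {
  fit <- lb_fit(make_hyperbola_curve(0.6, 2))
  expect_equal(fit$ei_max, 0.6, tolerance = 1e-12)
  expect_equal(fit$ss_half, 2, tolerance = 1e-12)
  expect_equal(fit$ratio, 2 / 0.6, tolerance = 1e-12)
  expect_identical(fit$ratio, fit$ss_half / fit$ei_max)  # stored exactly
  expect_equal(fit$n_used, 10L)

  set.seed(23)
  for (k in 1:25) {
    ei_max <- runif(1, 0.05, 0.95)
    ss_half <- runif(1, 0.1, 20)
    n <- sample(3:10, 1)
    ss <- sort(runif(n, 0.2, 60))
    f <- lb_fit(make_hyperbola_curve(ei_max, ss_half, ss = ss))
    expect_lt(abs(f$ei_max - ei_max) / ei_max, 1e-10)
    expect_lt(abs(f$ss_half - ss_half) / ss_half, 1e-10)
  }
})

test_that("Lineweaver-Burke fit is invariant to point ordering", {
  curve <- make_hyperbola_curve(0.55, 3.2)
  shuffled <- curve[sample(nrow(curve)), ]
  f1 <- lb_fit(curve)
  f2 <- lb_fit(shuffled)
  expect_equal(f1$ei_max, f2$ei_max)
  expect_equal(f1$ss_half, f2$ss_half)
})

test_that("points with non-positive EI are excluded with a warning", {
  curve <- make_hyperbola_curve(0.6, 2)
  curve$ei[7] <- -0.1
  expect_warning(fit <- lb_fit(curve), class = "oxyshear_exclusion_warning")
  expect_equal(fit$n_used, 9L)
  expect_equal(fit$n_excluded, 1L)
  # remaining points are still on the exact hyperbola
  expect_equal(fit$ei_max, 0.6, tolerance = 1e-10)
  expect_equal(fit$ss_half, 2, tolerance = 1e-10)
  expect_error(lb_fit(curve, exclusion_policy = "error"),
               class = "oxyshear_exclusion_error")
})

test_that("degenerate curves raise informative fit errors", {
  short <- make_hyperbola_curve(ss = c(1, 5, 20))
  short$ei[2] <- -0.05
  expect_warning(
    expect_error(lb_fit(short), class = "oxyshear_insufficient_data"),
    class = "oxyshear_exclusion_warning"
  )
  # 1/EI vs 1/SS line with negative intercept: EImax would be negative
  bad <- tibble::tibble(
    shear_stress_pa = c(0.125, 0.25, 0.5),
    ei = 1 / c(5.6, 2.6, 1.1),
    condition = "oxygenated", phase = "before_5Pa",
    subject = "S1", replicate = 1L
  )
  expect_error(lb_fit(bad), class = "oxyshear_nonphysical_fit")
})

test_that("protocol summary averages replicates then subjects", {
  one <- make_hyperbola_curve()
  s1 <- summarize_protocol(one)
  expect_equal(s1$mean_ei, one$ei)
  expect_true(all(s1$se_ei == 0))
  expect_true(all(s1$n == 1L))

  two <- dplyr::bind_rows(one, make_hyperbola_curve(subject = "S2"))
  s2 <- summarize_protocol(two)
  expect_true(all(s2$se_ei == 0))       # identical curves, zero spread
  expect_true(all(s2$n == 2L))

  mixed <- dplyr::bind_rows(one,
                            make_hyperbola_curve(ss = c(1, 2, 4, 8, 16),
                                                 subject = "S3"))
  expect_error(summarize_protocol(mixed), class = "oxyshear_grid_mismatch")
})

test_that("protocol summary recovers generator truth within sampling error", {
  for (seed in 1:3) {
    cfg <- synth_config(seed = seed)
    sm <- summarize_protocol(generate_dataset(cfg))
    truth <- dplyr::bind_rows(
      tibble::tibble(condition = "oxygenated",
                     shear_stress_pa = cfg$ss_grid,
                     truth = predict(cfg$truth_oxy, cfg$ss_grid)),
      tibble::tibble(condition = "deoxygenated",
                     shear_stress_pa = cfg$ss_grid,
                     truth = predict(cfg$truth_deoxy, cfg$ss_grid))
    )
    chk <- sm |>
      dplyr::filter(phase == "before_5Pa") |>
      dplyr::left_join(truth, by = c("condition", "shear_stress_pa"))
    # subject SD 0.01 over 10 subjects: deviations stay within ~4 SE
    expect_lt(max(abs(chk$mean_ei - chk$truth)), 0.015)
  }
})
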