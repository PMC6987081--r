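#' Configuration of the synthetic ektacytometry generator
#'
#' Defines the statistical structure of a synthetic LORRCA-like dataset
#' emulating the study design: 10 subjects measured in duplicate at the
#' 10 canonical shear-stress levels under oxygenated and deoxygenated
#' conditions, before and after 5 Pa / 300 s shear conditioning. Mean
#' curves follow the built-in two-term exponential presets; conditioning
#' adds a small EI increment at the low-stress levels (<= 1.65 Pa, where
#' the improvement is reported); between-subject variation is a shared
#' Gaussian offset per subject, and measurement noise is i.i.d. Gaussian.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_replicates Replicate measurements per subject (default 2).
#' @param ss_grid Shear-stress levels (Pa); default [ss_levels_pa].
#' @param truth_oxy,truth_deoxy Ground-truth calibrations for the two
#'   conditions; default the built-in presets.
#' @param after_ss_effect Additive EI shift at `ss <= 1.65` Pa for the
#'   after-conditioning phase (default +0.01).
#' @param subject_sd Between-subject SD of EI (default 0.01).
#' @param noise_sd Within-measurement SD of EI (default 0.005).
#' @param seed Integer seed (default 1).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10L, n_replicates = 2L,
                         ss_grid = ss_levels_pa,
                         truth_oxy = cal_preset("eq1_oxygenated"),
                         truth_deoxy = cal_preset("eq2_deoxygenated"),
                         after_ss_effect = 0.01,
                         subject_sd = 0.01, noise_sd = 0.005,
                         seed = 1L) {
  stopifnot(inherits(truth_oxy, "ei_calibration"),
            inherits(truth_deoxy, "ei_calibration"))
  check_number(n_subjects, "n_subjects", lower = 1)
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(subject_sd, "subject_sd", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(after_ss_effect, "after_ss_effect")
  if (any(ss_grid <= 0) || is.unsorted(ss_grid, strictly = TRUE)) {
    abort("`ss_grid` must be strictly increasing and positive.")
  }
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_replicates = as.integer(n_replicates),
         ss_grid = ss_grid,
         truth_oxy = truth_oxy, truth_deoxy = truth_deoxy,
         after_ss_effect = after_ss_effect,
         subject_sd = subject_sd, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
  # mean curves (with the conditioning effect) must stay inside (0, 1)
  for (cal in list(truth_oxy, truth_deoxy)) {
    m <- predict(cal, ss_grid) + ifelse(ss_grid <= 1.65, after_ss_effect, 0)
    if (any(m <= 0) || any(m >= 1)) {
      abort("Configured effects push a mean EI outside (0, 1).",
            class = "oxyshear_config_error")
    }
  }
  cfg
}

#' Generate a synthetic deformability dataset
#'
#' Draws EI(ss) = truth_condition(ss) + conditioning effect + subject
#' offset + noise for every subject x condition x phase x replicate,
#' fully reproducible from the configured seed. The defaults yield
#' 10 x 2 x 2 x 2 = 80 curves on the canonical shear-stress ladder.
#'
#' @param cfg A [synth_config()].
#' @return A tibble in the standard curves layout: `shear_stress_pa`,
#'   `ei`, `condition`, `phase`, `subject`, `replicate`.
#' @examples
#' curves <- generate_dataset(synth_config(seed = 42))
#' dplyr::count(curves, condition, phase)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
    b_s <- stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd)
    names(b_s) <- subjects
    design <- tidyr::expand_grid(
      subject = subjects,
      condition = c("oxygenated", "deoxygenated"),
      phase = c("before_5Pa", "after_5Pa"),
      replicate = seq_len(cfg$n_replicates)
    )
    purrr::pmap(design, function(subject, condition, phase, replicate) {
      cal <- if (condition == "oxygenated") cfg$truth_oxy else cfg$truth_deoxy
      mu <- predict(cal, cfg$ss_grid) +
        ifelse(phase == "after_5Pa" & cfg$ss_grid <= 1.65,
               cfg$after_ss_effect, 0) +
        b_s[[subject]]
      tibble(
        shear_stress_pa = cfg$ss_grid,
        ei = mu + stats::rnorm(length(cfg$ss_grid), 0, cfg$noise_sd),
        condition = condition, phase = phase,
        subject = subject, replicate = as.integer(replicate)
      )
    }) |>
      purrr::list_rbind()
  })
}

# Template for the non-monotone ghost (haemoglobin-free resealed cell)
# mean curve: rises to ~0.3 by 2.91 Pa, then fragments and the apparent
# EI falls below zero above 5.15 Pa.
ghost_mean_ei <- function(ss) {
  peak <- 0.30
  rise <- peak * (1 - exp(-ss / 1.1))
  fall <- ifelse(ss > 2.91, 0.25 * log(ss / 2.91), 0)
  rise - fall
}

#' Generate synthetic ghost-cell deformability curves
#'
#' Resealed ghosts deteriorate at high shear: their apparent EI rises to
#' about 0.3 near 2.91 Pa and then decreases, crossing below zero above
#' 5.15 Pa as cells fragment. These curves exercise the EI <= 0 exclusion
#' path of the Lineweaver-Burke fit and the non-monotone-fit error path
#' of the calibration module.
#'
#' @param cfg A [synth_config()]; `n_subjects`, `n_replicates`,
#'   `ss_grid`, `noise_sd` and `seed` are used.
#' @return A tibble in the standard curves layout with
#'   `condition = "oxygenated"`, `phase = "before_5Pa"`.
#' @export
generate_ghost_curves <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed + 1L, {
    design <- tidyr::expand_grid(
      subject = sprintf("G%02d", seq_len(cfg$n_subjects)),
      replicate = seq_len(cfg$n_replicates)
    )
    purrr::pmap(design, function(subject, replicate) {
      mu <- ghost_mean_ei(cfg$ss_grid)
      noise_sd <- min(cfg$noise_sd, 0.02)
      tibble(
        shear_stress_pa = cfg$ss_grid,
        ei = mu + stats::rnorm(length(cfg$ss_grid), 0, noise_sd),
        condition = "oxygenated", phase = "before_5Pa",
        subject = subject, replicate = as.integer(replicate)
      )
    }) |>
      purrr::list_rbind()
  })
}
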