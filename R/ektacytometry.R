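#' Elongation index from diffraction-pattern axes
#'
#' The ektacytometer records the laser-diffraction pattern of sheared red
#' blood cells as an ellipse with vertical axis `a` and horizontal axis `b`
#' (same arbitrary length unit). The elongation index is the dimensionless
#' shape measure EI = (a - b) / (a + b): zero for a circular pattern,
#' positive when cells elongate along the flow, and antisymmetric under
#' swapping the axes.
#'
#' @param a Vertical axis length(s) of the diffraction pattern, > 0.
#' @param b Horizontal axis length(s), same units as `a`, > 0.
#'
#' @return Numeric vector of elongation indices in (-1, 1), recycled to the
#'   common length of `a` and `b`.
#' @examples
#' elongation_index(2, 2)   # 0
#' elongation_index(3, 1)   # 0.5
#' @export
elongation_index <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    abort("`a` and `b` must be numeric axis lengths.",
          class = "oxyshear_invalid_measurement")
  }
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    abort("Diffraction axes `a` and `b` must be finite and > 0.",
          class = "oxyshear_invalid_measurement")
  }
  (a - b) / (a + b)
}

#' Lineweaver-Burke parameterisation of a deformability curve
#'
#' Parameterises one EI-versus-shear-stress curve by the hyperbolic model
#' EI(SS) = EImax * SS / (SS12 + SS) through its Lineweaver-Burke
#' linearisation: an ordinary least-squares line of 1/EI against 1/SS gives
#' intercept 1/EImax and slope SS12/EImax. `EImax` is the asymptotic
#' maximal elongation, `SS12` (Pa) the shear stress at half-maximal
#' elongation, and `SS12/EImax` a normalised measure of `SS12`. Points with
#' EI <= 0 (ghost-fragmentation artifacts) cannot enter the linearisation
#' and are excluded with a warning.
#'
#' @param data A tibble holding exactly one curve, with columns
#'   `shear_stress_pa`, `ei`, `condition`, `phase`, `subject`, `replicate`.
#' @param exclusion_policy How to treat points with EI <= 0:
#'   `"exclude"` (default) drops them with a warning; `"error"` aborts if
#'   any are present.
#'
#' @return An object of class `lb_fit` with elements `ei_max`, `ss_half`
#'   (Pa), `ratio` (Pa, = `ss_half / ei_max`), `r2_linear`, `n_used`,
#'   `n_excluded` and the curve metadata. Use [tidy()] / [glance()] to get
#'   tibbles.
#' @examples
#' ss <- ss_levels_pa
#' curve <- tibble::tibble(
#'   shear_stress_pa = ss, ei = 0.6 * ss / (2 + ss),
#'   condition = "oxygenated", phase = "before_5Pa",
#'   subject = "S1", replicate = 1L
#' )
#' fit <- lb_fit(curve)
#' tidy(fit)
#' @export
lb_fit <- function(data, exclusion_policy = c("exclude", "error")) {
  check_single_curve(data)
  exclusion_policy <- match.arg(exclusion_policy)

  usable <- data$ei > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0L) {
    if (exclusion_policy == "error") {
      abort(sprintf("%d point(s) with EI <= 0 present and policy is 'error'.",
                    n_excluded),
            class = "oxyshear_exclusion_error")
    }
    warn(sprintf(
      "Excluding %d point(s) with EI <= 0 from the Lineweaver-Burke fit.",
      n_excluded), class = "oxyshear_exclusion_warning")
  }
  ss <- data$shear_stress_pa[usable]
  ei <- data$ei[usable]
  if (length(ss) < 3L) {
    abort(sprintf(
      "Need >= 3 points with EI > 0 for the Lineweaver-Burke fit, got %d.",
      length(ss)), class = "oxyshear_insufficient_data")
  }

  fit <- lm(y ~ x, data = data.frame(x = 1 / ss, y = 1 / ei))
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  if (!is.finite(intercept) || intercept <= 0) {
    abort(paste0(
      "Non-positive intercept in the linearised regression: the curve is ",
      "not hyperbola-like (EImax would be non-physical)."),
      class = "oxyshear_nonphysical_fit")
  }
  ei_max <- 1 / intercept
  ss_half <- slope / intercept
  y <- 1 / ei
  r2_linear <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)

  meta <- curve_keys(data)
  structure(
    list(
      ei_max = ei_max,
      ss_half = ss_half,
      ratio = ss_half / ei_max,
      r2_linear = r2_linear,
      n_used = length(ss),
      n_excluded = n_excluded,
      condition = meta$condition[1],
      phase = meta$phase[1],
      subject = meta$subject[1],
      replicate = meta$replicate[1]
    ),
    class = "lb_fit"
  )
}

#' @export
print.lb_fit <- function(x, ...) {
  cat("<lb_fit> Lineweaver-Burke deformability parameters\n")
  cat(sprintf("  subject %s | %s | %s | replicate %s\n",
              x$subject, x$condition, x$phase, x$replicate))
  cat(sprintf("  EImax = %.4f, SS1/2 = %.4f Pa, SS1/2/EImax = %.4f Pa\n",
              x$ei_max, x$ss_half, x$ratio))
  cat(sprintf("  linear R^2 = %.5f, n used = %d (excluded %d)\n",
              x$r2_linear, x$n_used, x$n_excluded))
  invisible(x)
}

#' @rdname lb_fit
#' @param x An `lb_fit` object.
#' @param ... Unused.
#' @method tidy lb_fit
#' @export
tidy.lb_fit <- function(x, ...) {
  tibble(
    term = c("ei_max", "ss_half_pa", "ratio_pa"),
    estimate = c(x$ei_max, x$ss_half, x$ratio)
  )
}

#' @rdname lb_fit
#' @method glance lb_fit
#' @export
glance.lb_fit <- function(x, ...) {
  tibble(
    subject = x$subject, condition = x$condition, phase = x$phase,
    replicate = x$replicate,
    ei_max = x$ei_max, ss_half_pa = x$ss_half, ratio_pa = x$ratio,
    r2_linear = x$r2_linear, n_used = x$n_used, n_excluded = x$n_excluded
  )
}

#' Lineweaver-Burke fits for every curve in a dataset
#'
#' Applies [lb_fit()] to each (subject, condition, phase, replicate) curve
#' in a long table of measurements and row-binds the [glance()] summaries.
#'
#' @inheritParams lb_fit
#' @param data Long tibble of measurements covering one or more curves.
#' @return A tibble with one row per curve: metadata plus `ei_max`,
#'   `ss_half_pa`, `ratio_pa`, `r2_linear`, `n_used`, `n_excluded`.
#' @export
lb_fit_curves <- function(data, exclusion_policy = c("exclude", "error")) {
  check_curves(data)
  exclusion_policy <- match.arg(exclusion_policy)
  data |>
    dplyr::group_by(.data$subject, .data$condition, .data$phase,
                    .data$replicate) |>
    dplyr::group_split() |>
    purrr::map(\(d) glance(lb_fit(d, exclusion_policy))) |>
    purrr::list_rbind()
}

#' Summarise deformability curves over subjects
#'
#' Group means and standard errors of EI per (condition, phase,
#' shear-stress level). Replicate measurements of the same subject are
#' averaged first; the standard error is then taken across subjects with
#' the n - 1 denominator, matching the usual presentation of ektacytometry
#' group data (mean +/- SE over subjects). With a single subject the SE is
#' reported as 0 by convention.
#'
#' @param data Long tibble of measurements; all curves must share the same
#'   shear-stress grid.
#' @return A tibble with columns `condition`, `phase`, `shear_stress_pa`,
#'   `n` (subjects), `mean_ei`, `se_ei`.
#' @export
summarize_protocol <- function(data) {
  check_curves(data)
  grids <- data |>
    dplyr::group_by(.data$subject, .data$condition, .data$phase,
                    .data$replicate) |>
    dplyr::summarise(grid = paste(signif(sort(.data$shear_stress_pa), 10),
                                  collapse = ","),
                     .groups = "drop")
  if (dplyr::n_distinct(grids$grid) > 1L) {
    abort("Curves use different shear-stress grids; cannot summarise.",
          class = "oxyshear_grid_mismatch")
  }
  data |>
    dplyr::group_by(.data$condition, .data$phase, .data$subject,
                    .data$shear_stress_pa) |>
    dplyr::summarise(ei = mean(.data$ei), .groups = "drop") |>
    dplyr::group_by(.data$condition, .data$phase, .data$shear_stress_pa) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ei = mean(.data$ei),
      se_ei = if (dplyr::n() > 1L) sd(.data$ei) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition, .data$phase, .data$shear_stress_pa)
}
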