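#' Casson blood rheology parameters
#'
#' Whole blood is modelled as a Casson fluid: a yield-stress,
#' shear-thinning material whose apparent viscosity is
#' \deqn{\mu(\dot\gamma) = \mu_\infty^2/\dot\gamma +
#'       2 \mu_\infty N_\infty / \sqrt{\dot\gamma} + N_\infty^2}
#' for positive shear rate, and a nominal 0.0035 Pa·s otherwise. Here
#' \eqn{\mu_\infty^2} is the Casson yield stress (Pa) and
#' \eqn{N_\infty^2} the infinite-shear (Casson) viscosity (Pa·s); both are
#' parameterised by the hematocrit.
#'
#' Two hematocrit parameterisations of the yield stress are provided.
#' `"literal"` takes \eqn{\mu_\infty = 0.625\,Hct} (in sqrt-Pa).
#' `"calibrated"` takes the cubic law
#' \eqn{\mu_\infty = \sqrt{0.1 (0.625\,Hct)^3}}, the classical
#' hematocrit-cubed yield-stress correlation; with it the default
#' viscosity cap 2.072e-2 Pa·s is reached near shear rate 0.15 1/s,
#' typical of near-stagnation zones. In both presets the Casson viscosity
#' is \eqn{N_\infty = \sqrt{\mu_0}\,(1-Hct)^{-0.25}} so the infinite-shear
#' viscosity is \eqn{\mu_0 (1-Hct)^{-0.5}}.
#'
#' @param hct Hematocrit fraction in (0, 1); default 0.4.
#' @param mu0 Plasma viscosity (Pa·s); default 1.45e-3.
#' @param preset `"literal"` (default) or `"calibrated"` yield-stress law.
#' @param mu_fallback Viscosity returned at non-positive shear rate
#'   (Pa·s); default 0.0035, nominal whole-blood viscosity.
#' @param mu_cap Optional upper viscosity bound (Pa·s) limiting stiffness
#'   near stagnation; default 2.072e-2. Use `NULL` or `Inf` to disable.
#'
#' @return An object of class `casson_params`.
#' @examples
#' p <- casson_params()
#' casson_derived(p)
#' apparent_viscosity(c(0, 1, 100, 1e6), p)
#' @export
casson_params <- function(hct = 0.4, mu0 = 1.45e-3,
                          preset = c("literal", "calibrated"),
                          mu_fallback = 0.0035, mu_cap = 2.072e-2) {
  preset <- match.arg(preset)
  check_number(hct, "hct", lower = 1e-12, upper = 1 - 1e-12)
  check_positive(mu0, "mu0")
  check_positive(mu_fallback, "mu_fallback")
  if (!is.null(mu_cap) && is.finite(mu_cap)) {
    check_positive(mu_cap, "mu_cap")
    if (mu_cap < mu_fallback) {
      abort("`mu_cap` must be >= `mu_fallback`.")
    }
  } else {
    mu_cap <- Inf
  }
  structure(
    list(hct = hct, mu0 = mu0, preset = preset,
         mu_fallback = mu_fallback, mu_cap = mu_cap),
    class = "casson_params"
  )
}

#' @export
print.casson_params <- function(x, ...) {
  d <- casson_derived(x)
  cat("<casson_params>\n")
  cat(sprintf("  Hct = %.3f, mu0 = %.4g Pa.s, preset = %s\n",
              x$hct, x$mu0, x$preset))
  cat(sprintf("  yield stress = %.4g Pa, infinite-shear viscosity = %.4g Pa.s\n",
              d$yield_stress, d$mu_high_shear))
  cat(sprintf("  fallback = %.4g Pa.s, cap = %.4g Pa.s\n",
              x$mu_fallback, x$mu_cap))
  invisible(x)
}

#' Derived Casson constants
#'
#' @param p A [casson_params()] object.
#' @return A list with `n_inf` (sqrt(Pa·s)), `mu_inf` (sqrt(Pa)),
#'   `yield_stress` (Pa, `mu_inf^2`) and `mu_high_shear` (Pa·s,
#'   `n_inf^2`, the infinite-shear limit).
#' @export
casson_derived <- function(p) {
  stopifnot(inherits(p, "casson_params"))
  n_inf <- sqrt(p$mu0) * (1 - p$hct)^(-0.25)
  mu_inf <- switch(p$preset,
    literal = 0.625 * p$hct,
    calibrated = sqrt(0.1 * (0.625 * p$hct)^3)
  )
  list(
    n_inf = n_inf,
    mu_inf = mu_inf,
    yield_stress = mu_inf^2,
    mu_high_shear = n_inf^2
  )
}

#' Casson apparent viscosity
#'
#' Piecewise apparent viscosity: the Casson law for positive shear rate,
#' the nominal fallback otherwise, then bounded above by `mu_cap`. With
#' zero yield stress the law reduces to the constant infinite-shear
#' viscosity (Newtonian limit).
#'
#' @param gamma_dot Shear rate(s), 1/s, finite.
#' @param p A [casson_params()] object.
#' @return Apparent viscosity (Pa·s), vectorised over `gamma_dot`.
#' @export
apparent_viscosity <- function(gamma_dot, p) {
  stopifnot(inherits(p, "casson_params"))
  if (!is.numeric(gamma_dot) || any(!is.finite(gamma_dot))) {
    abort("`gamma_dot` must be finite numeric shear rate in 1/s.")
  }
  d <- casson_derived(p)
  mu <- rep(p$mu_fallback, length(gamma_dot))
  pos <- gamma_dot > 0
  g <- gamma_dot[pos]
  mu[pos] <- d$yield_stress / g + 2 * d$mu_inf * d$n_inf / sqrt(g) +
    d$mu_high_shear
  pmin(mu, p$mu_cap)
}

#' Shear rate from a velocity-gradient tensor
#'
#' \eqn{\dot\gamma = \sqrt{2\, D:D}} with
#' \eqn{D = (\nabla u + \nabla u^T)/2} the rate-of-deformation tensor;
#' invariant under rigid rotations of the frame.
#'
#' @param grad_u Square 2x2 or 3x3 matrix of velocity gradients (1/s),
#'   entry `[i, j]` = du_i/dx_j.
#' @return Scalar shear rate (1/s), >= 0.
#' @examples
#' shear_rate(matrix(c(0, 0, 2, 0), 2, 2))  # simple shear du/dy = 2
#' @export
shear_rate <- function(grad_u) {
  if (!is.matrix(grad_u) || nrow(grad_u) != ncol(grad_u) ||
      !nrow(grad_u) %in% c(2L, 3L)) {
    abort("`grad_u` must be a square 2x2 or 3x3 matrix.",
          class = "oxyshear_shape_error")
  }
  if (any(!is.finite(grad_u))) abort("`grad_u` must be finite.")
  D <- (grad_u + t(grad_u)) / 2
  sqrt(2 * sum(D * D))
}
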