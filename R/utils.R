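# Internal helpers shared across modules.

# scalar type checks ---------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%g, %g], got %g.", name, lower, upper, x))
  }
  invisible(x)
}

check_positive <- function(x, name) check_number(x, name, lower = .Machine$double.xmin)

# curve tibbles --------------------------------------------------------------

curve_required_cols <- c("shear_stress_pa", "ei", "condition", "phase",
                         "subject", "replicate")

# Validate a curves tibble: required columns present, shear stress positive,
# EI in (-1, 1). Returns the data invisibly so it can be used in pipes.
check_curves <- function(data, name = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame of deformability measurements.", name))
  }
  missing_cols <- setdiff(curve_required_cols, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing_cols, collapse = ", ")),
          class = "oxyshear_schema_error")
  }
  if (any(!is.finite(data$shear_stress_pa)) || any(data$shear_stress_pa <= 0)) {
    abort("`shear_stress_pa` must be finite and > 0.",
          class = "oxyshear_value_error")
  }
  if (any(!is.finite(data$ei)) || any(data$ei <= -1) || any(data$ei >= 1)) {
    abort("`ei` must be finite and within (-1, 1).",
          class = "oxyshear_value_error")
  }
  invisible(data)
}

# One curve = one (subject, condition, phase, replicate) combination.
curve_keys <- function(data) {
  dplyr::distinct(data, .data$subject, .data$condition, .data$phase,
                  .data$replicate)
}

check_single_curve <- function(data, name = "data") {
  check_curves(data, name)
  if (nrow(curve_keys(data)) > 1L) {
    abort(sprintf(paste0(
      "`%s` contains more than one curve ",
      "(subject/condition/phase/replicate combination); ",
      "fit curves one at a time or use the *_curves() variant."), name))
  }
  invisible(data)
}

# Tridiagonal solver (Thomas algorithm): a sub-, b main, c super-diagonal.
solve_tridiag <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- c[1] / b[1]
  dp[1] <- d[1] / b[1]
  if (n > 1L) {
    for (i in 2:n) {
      m <- b[i] - a[i] * cp[i - 1]
      cp[i] <- c[i] / m
      dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
    }
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1L) {
    for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  }
  x
}

# Cumulative trapezoid of y over x, anchored at 0 for the first point.
cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

trapz1 <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}
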