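#' Plot group deformability curves
#'
#' EI versus shear stress (log scale) with mean ± SE per condition and
#' phase, the standard presentation of ektacytometry group data.
#'
#' @param summary Output of [summarize_protocol()].
#' @return A ggplot.
#' @export
plot_deformability <- function(summary) {
  stopifnot(all(c("condition", "phase", "shear_stress_pa", "mean_ei",
                  "se_ei") %in% names(summary)))
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$shear_stress_pa, .data$mean_ei,
                               colour = .data$condition,
                               linetype = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_ei - .data$se_ei,
                   ymax = .data$mean_ei + .data$se_ei),
      size = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Shear stress (Pa)", y = "Elongation index",
                  colour = "Condition", linetype = "Phase",
                  title = "RBC deformability curves (mean ± SE)")
}

#' Plot a cross-stream velocity profile
#'
#' @param field A `flow_field`.
#' @return A ggplot of u against the cross-stream coordinate.
#' @export
plot_velocity_profile <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  d <- tibble(y_m = field$y, u_m_s = field$u[, 1])
  ggplot2::ggplot(d, ggplot2::aes(.data$u_m_s, .data$y_m)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "u (m/s)",
                  y = if (field$geometry$type == "tube") "r (m)" else "y (m)",
                  title = sprintf("Velocity profile (t = %g s)", field$time))
}
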