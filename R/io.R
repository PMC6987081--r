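# CSV dialect for deformability curves and VTK legacy export of fields.

#' Read deformability curves from CSV
#'
#' Reads the standard curves dialect: header
#' `shear_stress_pa,ei,condition,phase,subject,replicate`, decimal point,
#' comma separator, UTF-8. Extra columns are tolerated (and reported);
#' a missing required column is a schema error; a non-numeric entry in a
#' numeric column is a row-level parse error naming the line.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of curves, row order preserved.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(curve_required_cols, header)
  if (length(missing_cols) > 0L) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "oxyshear_schema_error")
  }
  extra <- setdiff(header, curve_required_cols)
  if (length(extra) > 0L) {
    inform(sprintf("Ignoring extra column(s): %s.",
                   paste(extra, collapse = ", ")))
  }
  data <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      shear_stress_pa = readr::col_double(),
      ei = readr::col_double(),
      condition = readr::col_character(),
      phase = readr::col_character(),
      subject = readr::col_character(),
      replicate = readr::col_integer(),
      .default = readr::col_guess()
    ),
    na = character(),          # blank/NA entries are parse errors, not NAs
    show_col_types = FALSE
  ))
  probs <- readr::problems(data)
  if (nrow(probs) > 0L) {
    abort(sprintf(
      "Parse error in %s at line %d, column %d: expected %s, got '%s'.",
      path, probs$row[1], probs$col[1], probs$expected[1],
      probs$actual[1]), class = "oxyshear_parse_error")
  }
  check_curves(dplyr::select(data, dplyr::all_of(curve_required_cols)))
}

#' @rdname read_curves
#' @param data A curves tibble.
#' @return `write_curves()`: the path, invisibly.
#' @export
write_curves <- function(data, path) {
  check_curves(data)
  readr::write_csv(data, path)
  invisible(path)
}

# ---- VTK legacy export -----------------------------------------------------

format_vtk_values <- function(v, per_line = 6L) {
  s <- sprintf("%.9g", v)
  idx <- ceiling(seq_along(s) / per_line)
  vapply(split(s, idx), paste, character(1), collapse = " ")
}

vtk_scalar_block <- function(name, values) {
  c(sprintf("SCALARS %s double 1", name),
    "LOOKUP_TABLE default",
    format_vtk_values(values))
}

# One legacy ASCII STRUCTURED_POINTS file for a field; values are written
# x-fastest as VTK requires (our matrices are [y, x], so transpose).
write_vtk_field <- function(field, path, extra = list()) {
  nxp <- length(field$x); nyp <- length(field$y)
  arrays <- list(u = field$u, v = field$v, p = field$p,
                 gamma_dot = field$gamma_dot, mu = field$mu, tau = field$tau)
  arrays <- c(arrays, extra)
  lines <- c(
    "# vtk DataFile Version 3.0",
    sprintf("oxyshear flow field t=%.9g s", field$time),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", nxp, nyp),
    sprintf("ORIGIN %.9g %.9g 0", field$x[1], field$y[1]),
    sprintf("SPACING %.9g %.9g 1",
            field$x[2] - field$x[1], field$y[2] - field$y[1]),
    sprintf("POINT_DATA %d", nxp * nyp)
  )
  for (nm in names(arrays)) {
    lines <- c(lines, vtk_scalar_block(nm, as.vector(t(arrays[[nm]]))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export flow (and EI) fields as VTK legacy files
#'
#' Writes one ASCII `STRUCTURED_POINTS` file per stored phase with point
#' data `u, v, p, gamma_dot, mu, tau`, plus `ei_oxy`, `ei_deoxy` and
#' `ei_diff` when EI fields are supplied. Output is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param x A `flow_field` or `flow_series`.
#' @param dir Output directory (created if needed).
#' @param ei_oxy,ei_deoxy Optional `ei_field` (or list of them matching
#'   the phases) to append.
#' @param prefix File-name prefix (default `"field"`).
#' @return Character vector of file paths, invisibly.
#' @export
export_fields <- function(x, dir, ei_oxy = NULL, ei_deoxy = NULL,
                          prefix = "field") {
  fields <- if (inherits(x, "flow_field")) list(x) else x$fields
  as_list <- function(e) {
    if (is.null(e)) return(NULL)
    if (inherits(e, "ei_field")) list(e) else e
  }
  ei_oxy <- as_list(ei_oxy); ei_deoxy <- as_list(ei_deoxy)
  for (e in c(ei_oxy, ei_deoxy)) {
    if (!is.null(e) && !identical(dim(e$ei), dim(fields[[1]]$u))) {
      abort("EI field grid does not match the flow field grid.",
            class = "oxyshear_shape_error")
    }
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(fields))
  for (k in seq_along(fields)) {
    extra <- list()
    if (!is.null(ei_oxy)) extra$ei_oxy <- ei_oxy[[k]]$ei
    if (!is.null(ei_deoxy)) extra$ei_deoxy <- ei_deoxy[[k]]$ei
    if (!is.null(ei_oxy) && !is.null(ei_deoxy)) {
      extra$ei_diff <- ei_deoxy[[k]]$ei - ei_oxy[[k]]$ei
    }
    paths[k] <- file.path(dir, sprintf("%s_%04d.vtk", prefix, k))
    write_vtk_field(fields[[k]], paths[k], extra = extra)
  }
  invisible(paths)
}

#' @rdname export_fields
#' @param series A `flow_series`.
#' @param path CSV path for the wall-shear-stress profile (position,
#'   wall, WSS, phase time).
#' @export
export_wss <- function(series, path) {
  readr::write_csv(wall_shear_stress(series), path)
  invisible(path)
}
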