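#' Write a measurement series to tidy CSV
#'
#' Columns: `time_h`, `value`, `sd` (if present), `label`.
#'
#' @param series A [measurement_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(series, path) {
  stopifnot(inherits(series, "measurement_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement series from tidy CSV
#'
#' Expects columns `time_h` and `value` (or `cells_per_cm2`), optionally
#' `sd` and `label`.
#'
#' @param path CSV file path.
#' @param label Series label, used when the file carries none.
#' @return A [measurement_series()].
#' @export
read_measurement_csv <- function(path, label = "adsorption") {
  d <- utils::read.csv(path)
  value_col <- intersect(c("value", "cells_per_cm2"), names(d))
  if (!"time_h" %in% names(d) || length(value_col) == 0)
    stop("measurement CSV needs columns time_h and value (or cells_per_cm2)",
         call. = FALSE)
  lab <- if ("label" %in% names(d)) as.character(d$label[1]) else label
  measurement_series(d$time_h, d[[value_col[1]]],
                     sd = if ("sd" %in% names(d)) d$sd else NULL,
                     label = lab)
}

#' Write a protein trajectory to tidy CSV
#'
#' Columns: `time_h`, `mean_fluid_ug_per_mL`, `surface_ug_per_mm2`,
#' `mass_ug`. Set `full_field` to also write the depth-resolved
#' concentration matrix (rows = depth cells, columns = output times) next to
#' the tidy file.
#'
#' @param traj A `protein_trajectory`.
#' @param path Output CSV path.
#' @param full_field Write `<path base>_field.csv` with the full c(z, t)?
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, full_field = FALSE) {
  stopifnot(inherits(traj, "protein_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (full_field) {
    fp <- sub("\\.csv$", "_field.csv", path)
    field <- as.data.frame(traj$c)
    names(field) <- sprintf("t_%g", traj$times)
    field <- cbind(z_mm = traj$z_grid, field)
    utils::write.csv(field, fp, row.names = FALSE)
  }
  invisible(path)
}

# known top-level keys of the run configuration
run_config_keys <- c("geometry", "protein", "cell", "transfer", "scenarios",
                     "schedules", "noise", "output_dir", "seed")

#' Read and validate a run configuration
#'
#' Configuration files drive the analysis scripts: a YAML (or JSON) mapping
#' with unit-suffixed keys, e.g.
#' `protein: {k_a_mL_per_ug_h: 6.2e-4, k_d_per_h: 0.2, c_s_max_ug_per_mm2: 31.5, D_mm2_per_h: 0.3}`.
#' Unknown top-level keys are rejected so typos fail loudly. See
#' `system.file("extdata", "default_config.yaml", package = "sorbcell")` for
#' the documented schema.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list with classes resolved: `geometry` as
#'   [well_geometry()], `protein` as [protein_params()], `cell` as
#'   [cell_params()], `transfer` as [transfer_function()] (when present),
#'   plus the remaining raw entries.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  out <- raw
  if (!is.null(raw$geometry))
    out$geometry <- well_geometry(
      fluid_volume_uL = raw$geometry$fluid_volume_uL,
      disk_diameter_mm = raw$geometry$disk_diameter_mm)
  if (!is.null(raw$protein))
    out$protein <- protein_params(
      k_a = raw$protein$k_a_mL_per_ug_h,
      k_d = raw$protein$k_d_per_h,
      c_s_max = raw$protein$c_s_max_ug_per_mm2,
      D = if (is.null(raw$protein$D_mm2_per_h)) 0.3
          else raw$protein$D_mm2_per_h)
  if (!is.null(raw$cell))
    out$cell <- cell_params(
      gamma = raw$cell$gamma,
      c_0 = raw$cell$c_0_cells_per_cm2,
      c_m = if (is.null(raw$cell$c_m_cells_per_cm2))
        cell_capacity(25) else raw$cell$c_m_cells_per_cm2,
      k = raw$cell$k_cm2_per_cells_h)
  # YAML sequences mixing ints and floats come back as lists; flatten the
  # numeric-vector entries
  if (!is.null(raw$schedules))
    out$schedules <- lapply(raw$schedules, function(x) as.numeric(unlist(x)))
  if (!is.null(raw$scenarios))
    out$scenarios <- lapply(raw$scenarios, function(x) as.numeric(unlist(x)))
  if (!is.null(raw$transfer))
    out$transfer <- transfer_function(
      a = raw$transfer$a_cm2_per_cells_h,
      b = raw$transfer$b_mm2_per_ug,
      form = if (is.null(raw$transfer$form)) "exponential"
             else raw$transfer$form)
  out
}

#' Write a fit or run summary as JSON
#'
#' @param x A named list (numbers, strings, vectors).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
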