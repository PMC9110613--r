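# File formats: the versioned time-point CSV, fit records as JSON,
# template CSV, and the YAML workflow configuration.

.TIMEPOINT_COLS <- c("cohort_id", "patient_id", "cycle_id", "injected_MBq",
                     "voi", "t_hours", "odr_mGy_per_s", "slot")
.SCHEMA_VERSION <- "tdrcdose-timepoints-1"

.check_measurements <- function(df) {
  missing_cols <- setdiff(.TIMEPOINT_COLS, names(df))
  if (length(missing_cols)) {
    .stop(sprintf("measurement table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")), "schema_error")
  }
  invisible(df)
}

#' Read and write the time-point measurement table
#'
#' The measurement CSV is the package's interchange format: one row per
#' acquisition with columns `cohort_id`, `patient_id`, `cycle_id`,
#' `injected_MBq`, `voi`, `t_hours`, `odr_mGy_per_s`, `slot`, preceded by
#' a `# schema:` comment line. Round-trips are lossless (times and dose
#' rates written with full precision).
#'
#' @param df Measurement data frame (schema above).
#' @param path CSV path.
#' @return `write_timepoints()` returns `path` invisibly;
#'   `read_timepoints()` the data frame.
#' @export
write_timepoints <- function(df, path) {
  .check_measurements(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema: %s", .SCHEMA_VERSION), con)
  write.csv(format(df[, .TIMEPOINT_COLS], digits = 17, trim = TRUE,
                   scientific = NA),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timepoints
#' @export
read_timepoints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    read.csv(text = paste(body, collapse = "\n"),
             colClasses = c(cohort_id = "character",
                            patient_id = "character", cycle_id = "integer",
                            injected_MBq = "numeric", voi = "character",
                            t_hours = "numeric",
                            odr_mGy_per_s = "numeric", slot = "character")),
    error = function(e) .stop(sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e)), "schema_error"))
  .check_measurements(df)
  bad <- which(!is.finite(df$t_hours) | df$t_hours <= 0 |
                 !is.finite(df$odr_mGy_per_s) | df$odr_mGy_per_s < 0)
  if (length(bad)) {
    .stop(sprintf("invalid rows (1-based data lines): %s",
                  paste(bad, collapse = ", ")), "schema_error")
  }
  df
}

#' Serialize fit results to JSON
#'
#' @param fits Named list of `tdrc_fit` objects (names identify
#'   patient/cycle/VOI).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  rec <- lapply(fits, function(f) {
    list(params = triexp_params_record(f$params),
         dose_Gy = f$dose_Gy,
         residuals_mGy_per_s = f$residuals,
         first_point_gap_mGy_per_s = f$first_point_gap,
         converged = f$converged,
         data = f$data)
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write a population template as two-column CSV
#'
#' Columns `t_hours` and `odr_mGy_per_s_per_MBq`.
#'
#' @param template A [build_population_template()] result.
#' @param path CSV path.
#' @param voi_label Label to attach on read.
#' @return `write_template_csv()` returns `path` invisibly;
#'   `read_template_csv()` a `population_template`.
#' @export
write_template_csv <- function(template, path) {
  df <- data.frame(t_hours = template$time_h,
                   odr_mGy_per_s_per_MBq = template$curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_contributors: %d", template$n_contributors), con)
  write.csv(format(df, digits = 17, trim = TRUE), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_template_csv
#' @export
read_template_csv <- function(path, voi_label = NA) {
  lines <- readLines(path, warn = FALSE)
  nc <- sub("# n_contributors: *", "",
            grep("^# n_contributors:", lines, value = TRUE)[1L])
  df <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  grid <- df$t_hours
  structure(list(time_h = grid, curve = df$odr_mGy_per_s_per_MBq,
                 n_contributors = if (is.na(nc)) NA_integer_
                                  else as.integer(nc),
                 contributors = NULL, voi_label = voi_label,
                 grid_step_h = if (length(grid) > 1L) grid[2L] - grid[1L]
                               else NA_real_),
            class = "population_template")
}

#' Workflow configuration
#'
#' All tunables of the adaptive workflow in one place, round-trippable
#' through YAML.
#'
#' @param tol_first_point Fit tolerance on the earliest point (mGy/s).
#' @param template_grid_step_h Population-template grid step (h).
#' @param donor_policy M1 donor selection: `"nearest"` or `"next-first"`.
#' @param reference_cycle_policy M2 reference cycle: `"earliest-3pt"`.
#' @param half_life_hours Physical half-life (h) used for `lam`.
#' @param seed Seed for the deterministic multi-start fits.
#' @param routing Method priority for the adaptive routing, most preferred
#'   first.
#' @param boundary_hours Late zero-boundary time (h).
#' @return A list of class `workflow_config`.
#' @export
workflow_config <- function(tol_first_point = 1e-5,
                            template_grid_step_h = 0.1,
                            donor_policy = "nearest",
                            reference_cycle_policy = "earliest-3pt",
                            half_life_hours = 6.6443 * 24,
                            seed = 42L,
                            routing = c("TRIEXP_REF", "M1", "M2", "M3"),
                            boundary_hours = 600) {
  structure(list(tol_first_point = tol_first_point,
                 template_grid_step_h = template_grid_step_h,
                 donor_policy = donor_policy,
                 reference_cycle_policy = reference_cycle_policy,
                 half_life_hours = half_life_hours,
                 seed = as.integer(seed),
                 routing = routing,
                 boundary_hours = boundary_hours),
            class = "workflow_config")
}

#' @rdname workflow_config
#' @param config A `workflow_config`.
#' @param path YAML file path.
#' @export
write_workflow_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname workflow_config
#' @export
read_workflow_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(workflow_config, vals)
}
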