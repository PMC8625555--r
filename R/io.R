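# CSV/JSON/YAML readers and writers for the pipeline's table formats.
# All CSV I/O is locale-independent: period decimal separator, UTF-8.

curve_id_cols <- c("participant_id", "test_type", "tier_g", "rep")

#' Read and write glucose curve tables
#'
#' Wide CSV format: one row per test with identifier columns
#' (`participant_id`, `group`, `test_type` = reference|meal, `meal_id`,
#' `tier_g`, `rep`) and one glucose column per grid time (`t0`, `t15`,
#' ...). Write-then-read is the identity on values.
#'
#' @param path File path.
#' @param time_grid Measurement times matching the `t*` columns.
#' @return `read_curves()` returns a tibble; writers return their input
#'   invisibly.
#' @export
read_curves <- function(path, time_grid = default_time_grid()) {
  curves <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    test_type = readr::col_character(),
    meal_id = readr::col_integer(),
    .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
  stop_on_parse_problems(curves, path)
  check_columns(curves, c(curve_id_cols, time_cols(time_grid)),
                sprintf("curve file '%s'", path))
  bad <- !curves$test_type %in% c("reference", "meal")
  if (any(bad)) {
    abort(sprintf("%s: invalid test_type at data row(s) %s.",
                  path, paste(head(which(bad), 5), collapse = ", ")),
          class = "glload_schema_error")
  }
  curves
}

#' @rdname read_curves
#' @param curves Curve table.
#' @export
write_curves <- function(curves, path, time_grid = default_time_grid()) {
  check_columns(curves, c(curve_id_cols, time_cols(time_grid)), "curve table")
  readr::write_csv(curves, path, progress = FALSE)
  invisible(curves)
}

#' Read and write meal nutrient tables
#'
#' CSV with `meal_id`, `name`, `kcal`, `carb_g`, `fiber_g`, `sugars_g`,
#' `protein_g`, `fat_g`, `tier_g`. Missing sugars values (printed "N/A"
#' on some labels) are parsed as `NA`, never as zero; sugars are not a
#' model term so they never enter computation.
#'
#' @param path File path.
#' @return `read_meals()` returns a tibble; `write_meals()` its input,
#'   invisibly.
#' @export
read_meals <- function(path) {
  meals <- readr::read_csv(path, col_types = readr::cols(
    meal_id = readr::col_integer(),
    name = readr::col_character(),
    .default = readr::col_double()
  ), na = c("", "NA", "N/A"), progress = FALSE)
  stop_on_parse_problems(meals, path)
  check_columns(meals, c("meal_id", "carb_g", "fiber_g", "protein_g",
                         "fat_g", "tier_g"),
                sprintf("meal file '%s'", path))
  if (any(meals$fiber_g > meals$carb_g, na.rm = TRUE)) {
    abort(sprintf("%s: fiber_g exceeds carb_g.", path),
          class = "glload_schema_error")
  }
  meals
}

#' @rdname read_meals
#' @param meals Meal table.
#' @export
write_meals <- function(meals, path) {
  readr::write_csv(meals, path, progress = FALSE)
  invisible(meals)
}

#' Read and write glycemic record tables
#'
#' One row per participant x meal with `iauc`, `ref_iauc`, `gi`, `gl` and
#' the meal nutrients, as produced by [glycemic_records()] (plus the
#' `excluded` / `exclusion_reason` columns after filtering).
#'
#' @param path File path.
#' @return `read_records()` returns a tibble; `write_records()` its
#'   input, invisibly.
#' @export
read_records <- function(path) {
  records <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    meal_id = readr::col_integer(),
    .default = readr::col_guess()
  ), na = c("", "NA"), progress = FALSE)
  stop_on_parse_problems(records, path)
  check_columns(records, c("participant_id", "meal_id", "iauc", "gi", "gl"),
                sprintf("record file '%s'", path))
  records
}

#' @rdname read_records
#' @param records Record table.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(records)
}

stop_on_parse_problems <- function(df, path) {
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "%s: %d parse problem(s); first at row %d, column %s (%s).",
      path, nrow(probs), probs$row[1], probs$col[1], probs$expected[1]
    ), class = "glload_parse_error")
  }
  invisible(df)
}

#' Serialise a GL formula (or coefficient list) to JSON
#'
#' Coefficients are written at full double precision so a round trip is
#' lossless.
#'
#' @param formula A [gl_formula()].
#' @param path File path.
#' @return The formula / path, invisibly.
#' @export
write_gl_formula <- function(formula, path) {
  jsonlite::write_json(unclass(formula), path, auto_unbox = TRUE, digits = NA)
  invisible(formula)
}

#' @rdname write_gl_formula
#' @export
read_gl_formula <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gl_formula(x$intercept, x$coef_carb, x$coef_fat, x$coef_protein2,
             x$coef_fiber2, version = x$version %||% "custom")
}

#' Write a synthetic study to disk
#'
#' Writes `curves.csv`, `meals.csv`, a `truth.json` sidecar with the
#' generating parameters, and a `manifest.json` run manifest.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_curves(study$curves, file.path(dir, "curves.csv"),
               study$config$time_grid)
  write_meals(study$meals, file.path(dir, "meals.csv"))
  jsonlite::write_json(
    list(coefficients = as.list(study$truth$coefficients),
         iauc_scale = study$truth$iauc_scale,
         participant_sd = study$truth$participant_sd,
         residual_sd = study$truth$residual_sd,
         ref_iauc_by_tier = as.list(study$truth$ref_iauc_by_tier)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  write_manifest(file.path(dir, "manifest.json"), stage = "simulate",
                 seed = study$config$seed,
                 counts = list(participants = nrow(study$participants),
                               meals = nrow(study$meals),
                               curves = nrow(study$curves)))
  invisible(dir)
}

#' Write a JSON run manifest
#'
#' Records the stage, seed, package version and row counts of a pipeline
#' step, for reproducibility audits.
#'
#' @param path Output path.
#' @param stage Stage name (e.g. "simulate", "compute").
#' @param seed Seed used, if any.
#' @param counts Named list of row counts.
#' @param inputs Named list of input file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, seed = NULL, counts = list(),
                           inputs = list()) {
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         package = "glload",
         version = as.character(utils::packageVersion("glload")),
         counts = counts, inputs = inputs),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "glload_config_error")
  }
  if (!is.null(vals$ref_iauc_by_tier)) {
    vals$ref_iauc_by_tier <- unlist(vals$ref_iauc_by_tier)
  }
  if (!is.null(vals$true_coefficients)) {
    vals$true_coefficients <- unlist(vals$true_coefficients)
  }
  do.call(sim_config, vals)
}
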