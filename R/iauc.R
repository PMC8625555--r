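#' Incremental area under a glucose curve
#'
#' Computes the incremental area under the curve (iAUC) of a postprandial
#' glucose trajectory: the exact integral of the piecewise-linear
#' interpolant of `glucose`, counting only the portion above the fasting
#' baseline (the reading at the first time point). Area below baseline is
#' ignored, not netted; a segment that crosses the baseline contributes
#' only its triangular part above it. This is the standard incremental
#' (cut-off) method used for glycemic index determination.
#'
#' @param times Numeric vector of measurement times in minutes, strictly
#'   increasing, starting at 0.
#' @param glucose Numeric vector of glucose readings (mg/dL), same length
#'   as `times`; the first reading is the fasting baseline.
#' @return iAUC in mg·min/dL (non-negative scalar).
#' @examples
#' incremental_auc(c(0, 15, 30, 45, 60, 90, 120),
#'                 c(90, 110, 120, 110, 100, 95, 90))
#' @export
incremental_auc <- function(times, glucose) {
  if (length(times) < 2) {
    abort("incremental_auc() needs at least 2 time points.",
          class = "glload_input_error")
  }
  if (length(times) != length(glucose)) {
    abort("`times` and `glucose` must have the same length.",
          class = "glload_input_error")
  }
  if (any(!is.finite(times)) || any(!is.finite(glucose))) {
    abort("`times` and `glucose` must be finite.", class = "glload_input_error")
  }
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.", class = "glload_input_error")
  }
  inc <- glucose - glucose[1]
  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    a <- inc[i]; b <- inc[i + 1L]; h <- times[i + 1L] - times[i]
    if (a >= 0 && b >= 0) {
      total <- total + h * (a + b) / 2
    } else if (a > 0 && b < 0) {
      # crosses baseline going down: triangle above baseline
      total <- total + a^2 * h / (2 * (a - b))
    } else if (a < 0 && b > 0) {
      # crosses going up
      total <- total + b^2 * h / (2 * (b - a))
    }
    # both <= 0: contributes nothing
  }
  total
}

#' Add per-curve iAUC to a curve table
#'
#' Vectorised convenience over [incremental_auc()]: takes a wide curve
#' table (one row per test, glucose readings in `t0`, `t15`, ... columns)
#' and appends an `iauc` column.
#'
#' @param curves Data frame of curves in the wide format written by
#'   [simulate_study()] / read by [read_curves()].
#' @param time_grid Measurement times matching the `t*` columns.
#' @return `curves` as a tibble with an added `iauc` column (mg·min/dL).
#' @export
add_iauc <- function(curves, time_grid = default_time_grid()) {
  tc <- time_cols(time_grid)
  check_columns(curves, tc, "curve table")
  g <- as.matrix(curves[, tc])
  curves <- tibble::as_tibble(curves)
  curves$iauc <- vapply(
    seq_len(nrow(g)),
    function(i) incremental_auc(time_grid, g[i, ]),
    numeric(1)
  )
  curves
}

#' Per-participant reference iAUC
#'
#' Averages a participant's duplicate sugar-solution reference curves at
#' one carbohydrate tier. The sugar solution at each tier (25/50/75 g) is
#' the GI denominator; each participant drinks it twice per tier.
#'
#' @param curves Curve table including reference rows
#'   (`test_type == "reference"`).
#' @param participant_id,tier_g The participant and carbohydrate tier (g).
#' @param time_grid Measurement times.
#' @return Mean reference iAUC (mg·min/dL) over that participant's repeats.
#' @export
reference_iauc <- function(curves, participant_id, tier_g,
                           time_grid = default_time_grid()) {
  check_columns(curves, c("participant_id", "test_type", "tier_g"), "curve table")
  sel <- curves[curves$test_type == "reference" &
                  curves$participant_id == participant_id &
                  curves$tier_g == tier_g, , drop = FALSE]
  if (nrow(sel) == 0) {
    abort(sprintf(
      "No reference curve for participant '%s' at tier %s g.",
      participant_id, tier_g
    ), class = "glload_missing_reference")
  }
  if (nrow(sel) == 1) {
    warn(sprintf(
      "Single reference repeat for participant '%s' at tier %s g; using it as-is.",
      participant_id, tier_g
    ))
  }
  if (!"iauc" %in% names(sel)) sel <- add_iauc(sel, time_grid)
  mean(sel$iauc)
}

#' Reference iAUC lookup table
#'
#' Computes the mean reference (sugar-solution) iAUC for every
#' participant-by-tier combination present in a curve table.
#'
#' @inheritParams add_iauc
#' @return Tibble with `participant_id`, `tier_g`, `ref_iauc`, `n_repeats`.
#' @export
reference_iauc_table <- function(curves, time_grid = default_time_grid()) {
  check_columns(curves, c("participant_id", "test_type", "tier_g"), "curve table")
  refs <- dplyr::filter(curves, .data$test_type == "reference")
  if (!"iauc" %in% names(refs)) refs <- add_iauc(refs, time_grid)
  dplyr::summarise(
    dplyr::group_by(refs, .data$participant_id, .data$tier_g),
    ref_iauc = mean(.data$iauc),
    n_repeats = dplyr::n(),
    .groups = "drop"
  )
}

#' Glycemic index
#'
#' GI = 100 x (iAUC after the test food) / (iAUC after the
#' carbohydrate-matched sugar reference), computed within participant.
#'
#' @param food_iauc,ref_iauc iAUC values in mg·min/dL; `ref_iauc` must be
#'   positive. Both vectorised.
#' @return GI in percent.
#' @examples
#' compute_gi(1424, 2754)
#' @export
compute_gi <- function(food_iauc, ref_iauc) {
  if (any(!is.finite(ref_iauc)) || any(ref_iauc <= 0)) {
    abort("`ref_iauc` must be positive: degenerate reference response.",
          class = "glload_degenerate_reference")
  }
  if (any(food_iauc < 0)) {
    abort("`food_iauc` must be non-negative.", class = "glload_input_error")
  }
  100 * food_iauc / ref_iauc
}

#' Glycemic load
#'
#' GL = GI x available carbohydrate / 100, where available (net)
#' carbohydrate is total carbohydrate minus dietary fiber.
#'
#' @param gi Glycemic index (percent), vectorised.
#' @param carb_g Total carbohydrate (g).
#' @param fiber_g Dietary fiber (g); must not exceed `carb_g`.
#' @return GL (dimensionless).
#' @examples
#' compute_gl(53, carb_g = 26, fiber_g = 2)
#' @export
compute_gl <- function(gi, carb_g, fiber_g) {
  if (any(gi < 0)) abort("`gi` must be non-negative.", class = "glload_input_error")
  if (any(fiber_g < 0) || any(carb_g < 0)) {
    abort("nutrient masses must be non-negative.", class = "glload_input_error")
  }
  if (any(fiber_g > carb_g)) {
    abort("`fiber_g` cannot exceed `carb_g`.", class = "glload_input_error")
  }
  gi * (carb_g - fiber_g) / 100
}

#' Per-participant glycemic records
#'
#' The core derivation step: for every meal test curve, computes its iAUC,
#' looks up the participant's tier-matched mean sugar reference, and
#' derives GI and GL. GI is computed per participant against that
#' participant's own reference (not as a ratio of meal means).
#'
#' @param curves Curve table containing both reference and meal rows.
#' @param meals Meal nutrient table (`meal_id`, `carb_g`, `fiber_g`, ...).
#' @param time_grid Measurement times.
#' @return Tibble with one row per participant x meal test:
#'   `participant_id`, `meal_id`, `tier_g`, `iauc`, `ref_iauc`, `gi`, `gl`
#'   plus the meal's nutrients.
#' @export
glycemic_records <- function(curves, meals, time_grid = default_time_grid()) {
  check_columns(curves, c("participant_id", "test_type", "tier_g"), "curve table")
  check_columns(meals, c("meal_id", "carb_g", "fiber_g", "protein_g", "fat_g"),
                "meal table")
  meal_tests <- dplyr::filter(curves, .data$test_type == "meal")
  unknown <- setdiff(unique(meal_tests$meal_id), meals$meal_id)
  if (length(unknown) > 0) {
    abort(sprintf("Curve rows reference unknown meal_id: %s",
                  paste(unknown, collapse = ", ")),
          class = "glload_join_error")
  }
  meal_tests <- add_iauc(meal_tests, time_grid)
  refs <- reference_iauc_table(curves, time_grid)
  rec <- dplyr::inner_join(meal_tests, refs, by = c("participant_id", "tier_g"))
  if (nrow(rec) < nrow(meal_tests)) {
    missing <- dplyr::anti_join(meal_tests, refs,
                                by = c("participant_id", "tier_g"))
    abort(sprintf(
      "No reference curves for %d meal test(s), e.g. participant '%s' tier %s g.",
      nrow(missing), missing$participant_id[1], missing$tier_g[1]
    ), class = "glload_missing_reference")
  }
  rec <- dplyr::inner_join(
    rec,
    dplyr::select(meals, "meal_id", "carb_g", "fiber_g", "protein_g", "fat_g"),
    by = "meal_id"
  )
  rec$gi <- compute_gi(rec$iauc, rec$ref_iauc)
  rec$gl <- compute_gl(rec$gi, rec$carb_g, rec$fiber_g)
  dplyr::select(
    rec, "participant_id", "meal_id", "tier_g", "iauc", "ref_iauc",
    "gi", "gl", "carb_g", "fiber_g", "protein_g", "fat_g"
  )
}

#' Meal-level summaries of iAUC, GI and GL
#'
#' Means and sample standard deviations (denominator n - 1) of iAUC, GI
#' and GL across the participants who consumed each meal. Records flagged
#' `excluded` are dropped first when the flag is present.
#'
#' @param records Record table from [glycemic_records()] (optionally after
#'   [apply_exclusions()]).
#' @return Tibble with one row per meal: `meal_id`, `n`, `iauc_mean`,
#'   `iauc_sd`, `gi_mean`, `gi_sd`, `gl_mean`, `gl_sd`. For single-record
#'   meals the SD is reported as 0 (flagged via `single_record`).
#' @export
summarize_meals <- function(records) {
  check_columns(records, c("meal_id", "iauc", "gi", "gl"), "record table")
  if ("excluded" %in% names(records)) {
    records <- dplyr::filter(records, !.data$excluded)
  }
  if (nrow(records) == 0) {
    abort("No retained records to summarise.", class = "glload_empty_summary")
  }
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  dplyr::summarise(
    dplyr::group_by(records, .data$meal_id),
    n = dplyr::n(),
    iauc_mean = mean(.data$iauc), iauc_sd = sd0(.data$iauc),
    gi_mean = mean(.data$gi), gi_sd = sd0(.data$gi),
    gl_mean = mean(.data$gl), gl_sd = sd0(.data$gl),
    single_record = dplyr::n() < 2,
    .groups = "drop"
  )
}
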