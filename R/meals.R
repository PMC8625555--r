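#' The 32-meal ready-to-eat study table
#'
#' The packaged per-meal table from the feeding study: nutrition-label
#' composition (kcal, total carbohydrate, fiber, sugars, protein, fat, in
#' grams), the carbohydrate tier (25/50/75 g), and the printed meal-level
#' summaries — sugar-reference iAUC, meal iAUC (mean +/- SD, mg·min/dL),
#' GI (%) and GL. Values are transcribed as printed; one sugars cell is
#' missing (`NA`) and a few GI SD cells are typographically implausible
#' and flagged via `gi_sd_anomaly` rather than corrected.
#'
#' @return Tibble with 32 rows.
#' @examples
#' rte_meals()[1, c("name", "carb_g", "fiber_g", "gi_mean", "gl_mean")]
#' @export
rte_meals <- function() {
  path <- system.file("extdata", "rte_meals.csv", package = "glload",
                      mustWork = TRUE)
  readr::read_csv(
    path,
    col_types = readr::cols(
      meal_id = readr::col_integer(),
      name = readr::col_character(),
      sig = readr::col_character(),
      gi_sd_anomaly = readr::col_logical(),
      .default = readr::col_double()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
}

#' GL self-consistency of the printed meal table
#'
#' For each meal, compares the printed GL mean with GI mean x available
#' carbohydrate / 100 recomputed from the printed GI and nutrients. Rows
#' differing by more than `tol` are flagged: these reflect the upstream
#' convention of averaging unrounded per-participant GLs, so the printed
#' (rounded) GI need not reproduce the printed GL exactly.
#'
#' @param meals The table from [rte_meals()] (or any table with
#'   `gi_mean`, `gl_mean`, `carb_g`, `fiber_g`).
#' @param tol Flagging threshold on the absolute difference (default 0.5).
#' @return Tibble with `meal_id`, `gl_printed`, `gl_recomputed`, `delta`,
#'   `consistent`.
#' @export
gl_consistency <- function(meals = rte_meals(), tol = 0.5) {
  check_columns(meals, c("meal_id", "gi_mean", "gl_mean", "carb_g", "fiber_g"),
                "meal table")
  recomputed <- compute_gl(meals$gi_mean, meals$carb_g, meals$fiber_g)
  tibble::tibble(
    meal_id = meals$meal_id,
    gl_printed = meals$gl_mean,
    gl_recomputed = recomputed,
    delta = recomputed - meals$gl_mean,
    consistent = abs(recomputed - meals$gl_mean) <= tol
  )
}
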