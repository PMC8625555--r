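#' Apply the study exclusion rules to glycemic records
#'
#' Flags per-participant records before model fitting, using the study's
#' cleaning rules, applied in order with the first matching rule recorded:
#'
#' 1. `fiber_iauc`: dietary fiber above 13 g *and* iAUC above
#'    4000 mg·min/dL (high response despite high fiber) — a conjunction;
#'    either condition alone retains the record;
#' 2. `gi_low`: GI strictly below 10 (theoretically insignificant);
#' 3. `gi_high`: GI strictly above 100.
#'
#' All boundaries are strict, so GI exactly 10 or exactly 100 is retained.
#' Filtering is at record (participant x meal) level because GI is a
#' per-participant quantity.
#'
#' @param records Record table with `gi` and `iauc` columns (and
#'   `fiber_g`, or join via `meals`).
#' @param meals Optional meal table supplying `fiber_g` when `records`
#'   lacks it.
#' @return A list of class `gl_filter`: `records` (input rows with added
#'   `excluded` flag and `exclusion_reason`), `retained` (surviving rows,
#'   input order preserved), and `report` (counts per rule plus excluded
#'   row ids; serialisable to JSON).
#' @examples
#' recs <- tibble::tibble(participant_id = "P01", meal_id = 1:3,
#'                        iauc = c(4100, 3900, 3000), gi = c(50, 50, 9.9),
#'                        fiber_g = c(16, 16, 2))
#' apply_exclusions(recs)$report
#' @export
apply_exclusions <- function(records, meals = NULL) {
  check_columns(records, c("gi", "iauc"), "record table")
  if (!"fiber_g" %in% names(records)) {
    if (is.null(meals)) {
      abort("`records` lacks `fiber_g`; supply `meals` to join it.",
            class = "glload_schema_error")
    }
    check_columns(meals, c("meal_id", "fiber_g"), "meal table")
    unknown <- setdiff(unique(records$meal_id), meals$meal_id)
    if (length(unknown) > 0) {
      abort(sprintf("Records reference unknown meal_id: %s",
                    paste(unknown, collapse = ", ")),
            class = "glload_join_error")
    }
    records <- dplyr::left_join(
      records, dplyr::select(meals, "meal_id", "fiber_g"), by = "meal_id"
    )
  }
  records <- tibble::as_tibble(records)
  reason <- rep(NA_character_, nrow(records))
  fib <- records$fiber_g > 13 & records$iauc > 4000
  lo <- records$gi < 10
  hi <- records$gi > 100
  reason[hi] <- "gi_high"
  reason[lo] <- "gi_low"
  reason[fib] <- "fiber_iauc"   # first rule wins, so assigned last
  records$excluded <- !is.na(reason)
  records$exclusion_reason <- reason

  ids <- if (all(c("participant_id", "meal_id") %in% names(records))) {
    paste(records$participant_id, records$meal_id, sep = ":")
  } else {
    as.character(seq_len(nrow(records)))
  }
  report <- list(
    n_input = nrow(records),
    n_excluded_fiber_iauc = sum(reason == "fiber_iauc", na.rm = TRUE),
    n_excluded_gi_low = sum(reason == "gi_low", na.rm = TRUE),
    n_excluded_gi_high = sum(reason == "gi_high", na.rm = TRUE),
    n_retained = sum(!records$excluded),
    excluded_ids = ids[records$excluded]
  )
  structure(
    list(records = records,
         retained = records[!records$excluded, , drop = FALSE],
         report = report),
    class = "gl_filter"
  )
}

#' @export
print.gl_filter <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<gl_filter> %d records: %d retained; excluded %d (fiber/iAUC), ",
           "%d (GI < 10), %d (GI > 100)\n"),
    r$n_input, r$n_retained, r$n_excluded_fiber_iauc,
    r$n_excluded_gi_low, r$n_excluded_gi_high
  ))
  invisible(x)
}
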