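#' GL prediction formula
#'
#' A GL prediction formula maps nutrition-label quantities to an expected
#' glycemic load:
#' `GL = intercept + coef_carb * (carb - fiber) + coef_fat * fat +
#' coef_protein2 * protein^2 + coef_fiber2 * fiber^2`.
#'
#' @param intercept,coef_carb,coef_fat,coef_protein2,coef_fiber2 Finite
#'   numeric coefficients (GL units; per g, or per g squared for the
#'   quadratic terms).
#' @param version Free-text tag recording the formula's provenance.
#' @return An object of class `gl_formula`.
#' @seealso [published_gl_formula()], [compose_gl_formula()],
#'   [predict_gl()]
#' @export
gl_formula <- function(intercept, coef_carb, coef_fat, coef_protein2,
                       coef_fiber2, version = "custom") {
  vals <- c(intercept, coef_carb, coef_fat, coef_protein2, coef_fiber2)
  if (any(!is.finite(vals))) {
    abort("All formula coefficients must be finite.",
          class = "glload_input_error")
  }
  structure(
    list(intercept = intercept, coef_carb = coef_carb, coef_fat = coef_fat,
         coef_protein2 = coef_protein2, coef_fiber2 = coef_fiber2,
         version = version),
    class = "gl_formula"
  )
}

#' @export
print.gl_formula <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<gl_formula '%s'> GL = %.*g + %.*g·availCarb + %.*g·fat + %.*g·protein² + %.*g·fiber²\n",
    x$version, digits, x$intercept, digits, x$coef_carb, digits, x$coef_fat,
    digits, x$coef_protein2, digits, x$coef_fiber2
  ))
  invisible(x)
}

#' The published GL prediction formula
#'
#' The frozen, published formula for estimating the glycemic load of a
#' mixed meal from its nutrition label:
#' `GL = 19.27 + 0.39 * available carbohydrate - 0.21 * fat -
#' 0.01 * protein^2 - 0.01 * fiber^2` (grams; available carbohydrate is
#' total carbohydrate minus fiber).
#'
#' @return A `gl_formula` tagged `"published-2021"`.
#' @examples
#' predict_gl(tibble::tibble(carb_g = 50, fiber_g = 2, protein_g = 4,
#'                           fat_g = 3))
#' @export
published_gl_formula <- function() {
  gl_formula(intercept = 19.27, coef_carb = 0.39, coef_fat = -0.21,
             coef_protein2 = -0.01, coef_fiber2 = -0.01,
             version = "published-2021")
}

# calibration envelope of available carbohydrate (g) spanned by the
# 32-meal study table; predictions outside it are extrapolations
.calibration_envelope <- c(20, 103)

#' Predict glycemic load from nutrition-label values
#'
#' Applies a [gl_formula()] to one or more meals. Sugars, if present, are
#' ignored: the formula has no sugars term. Predictions for meals whose
#' available carbohydrate falls outside the calibration envelope
#' (20-103 g) and negative predictions are returned as-is with a warning.
#'
#' @param meals Data frame (or named list) with `carb_g`, `fiber_g`,
#'   `protein_g`, `fat_g` in grams.
#' @param formula A `gl_formula`; defaults to the published one.
#' @return Numeric vector of predicted GL, one per meal row.
#' @examples
#' predict_gl(tibble::tibble(carb_g = 50, fiber_g = 2, protein_g = 4,
#'                           fat_g = 3), published_gl_formula())
#' @export
predict_gl <- function(meals, formula = published_gl_formula()) {
  if (!inherits(formula, "gl_formula")) {
    abort("`formula` must be a gl_formula object.", class = "glload_input_error")
  }
  if (!is.data.frame(meals)) meals <- tibble::as_tibble(as.list(meals))
  for (f in c("carb_g", "fiber_g", "protein_g", "fat_g")) {
    if (!f %in% names(meals) || anyNA(meals[[f]])) {
      abort(sprintf("Missing required nutrient field: %s", f),
            class = "glload_input_error")
    }
  }
  if (any(meals$carb_g < 0 | meals$fiber_g < 0 | meals$protein_g < 0 |
            meals$fat_g < 0)) {
    abort("Nutrient masses must be non-negative.", class = "glload_input_error")
  }
  if (any(meals$fiber_g > meals$carb_g)) {
    abort("`fiber_g` cannot exceed `carb_g`.", class = "glload_input_error")
  }
  ac <- meals$carb_g - meals$fiber_g
  out_of_range <- ac < .calibration_envelope[1] | ac > .calibration_envelope[2]
  if (any(out_of_range)) {
    warn(sprintf(
      "%d meal(s) outside the calibration envelope (available carbohydrate %g-%g g); predictions are extrapolations.",
      sum(out_of_range), .calibration_envelope[1], .calibration_envelope[2]
    ))
  }
  pred <- formula$intercept + formula$coef_carb * ac +
    formula$coef_fat * meals$fat_g +
    formula$coef_protein2 * meals$protein_g^2 +
    formula$coef_fiber2 * meals$fiber_g^2
  if (any(pred < 0)) {
    warn(sprintf("%d negative GL prediction(s): outside the formula's calibration.",
                 sum(pred < 0)))
  }
  pred
}

#' @rdname predict_gl
#' @param object A `gl_formula` (method for [stats::predict()]).
#' @param newdata Meal table passed to [predict_gl()].
#' @param ... Unused.
#' @export
predict.gl_formula <- function(object, newdata, ...) {
  predict_gl(newdata, object)
}

#' Predict GL for a table of meals
#'
#' Row-wise convenience over [predict_gl()]: returns the meal ids with
#' their predictions, order preserved. Per-row input problems are
#' reported with the offending row index.
#'
#' @inheritParams predict_gl
#' @return Tibble with `meal_id` and `predicted_gl` (empty for an empty
#'   input).
#' @export
predict_gl_table <- function(meals, formula = published_gl_formula()) {
  if (nrow(meals) == 0) {
    return(tibble::tibble(meal_id = integer(), predicted_gl = numeric()))
  }
  ids <- if ("meal_id" %in% names(meals)) meals$meal_id else seq_len(nrow(meals))
  preds <- purrr::imap_dbl(seq_len(nrow(meals)), function(i, ...) {
    tryCatch(
      predict_gl(meals[i, , drop = FALSE], formula),
      error = function(e) {
        abort(sprintf("Row %d: %s", i, conditionMessage(e)),
              class = "glload_input_error")
      }
    )
  })
  tibble::tibble(meal_id = ids, predicted_gl = preds)
}
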