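#' Fit the repeated-measures iAUC model
#'
#' Fits iAUC (on the working scale of `iauc_scale` mg·min/dL per unit) on
#' available carbohydrate (total minus fiber), fat, protein squared and
#' fiber squared, with a per-participant random intercept, by REML
#' ([lmerTest::lmer()]). Fixed-effect inference uses Wald t statistics
#' with Satterthwaite degrees of freedom: in this crossover design some
#' nutrient contrasts are partly between-participant, so normal-quantile
#' intervals would be too narrow.
#'
#' Degenerate designs fall back to ordinary least squares with a warning:
#' fewer than two participants, an essentially exact fit (zero residual
#' variance, as in noiseless synthetic data), or a singular fit in which
#' the participant variance collapses to zero.
#'
#' @param records Record table with `iauc`, `participant_id` and the meal
#'   nutrients (or supply `meals` to join them by `meal_id`).
#' @param meals Optional meal nutrient table.
#' @param iauc_scale mg·min/dL per working-scale unit (default 100, the
#'   scale on which the published coefficients live).
#' @return An object of class `iauc_model`: coefficients (named
#'   `intercept`, `carb`, `fat`, `protein2`, `fiber2`), `std_errors`,
#'   `p_values`, `participant_variance` and `residual_variance` (working
#'   scale), `method` ("reml" or "ols"), and the underlying `fit`.
#' @export
fit_iauc_model <- function(records, meals = NULL, iauc_scale = 100) {
  nutr <- c("carb_g", "fiber_g", "protein_g", "fat_g")
  if (!all(nutr %in% names(records))) {
    if (is.null(meals)) {
      abort("`records` lacks nutrient columns; supply `meals` to join them.",
            class = "glload_schema_error")
    }
    check_columns(meals, c("meal_id", nutr), "meal table")
    records <- dplyr::left_join(
      records, dplyr::select(meals, "meal_id", dplyr::all_of(nutr)),
      by = "meal_id"
    )
  }
  check_columns(records, c("iauc", "participant_id", nutr), "record table")
  dat <- tibble::tibble(
    y = records$iauc / iauc_scale,
    ac = records$carb_g - records$fiber_g,
    fat = records$fat_g,
    protein2 = records$protein_g^2,
    fiber2 = records$fiber_g^2,
    participant_id = factor(records$participant_id)
  )
  if (nrow(dat) < 5) {
    abort("Need at least 5 records to fit the iAUC model.",
          class = "glload_input_error")
  }
  X <- cbind(1, dat$ac, dat$fat, dat$protein2, dat$fiber2)
  if (qr(X)$rank < ncol(X)) {
    abort("Singular design: nutrient columns are linearly dependent.",
          class = "glload_singular_design")
  }

  ols <- lm(y ~ ac + fat + protein2 + fiber2, data = dat)
  noiseless <- sigma(ols) < 1e-8 * max(sd(dat$y), 1)
  single_participant <- nlevels(dat$participant_id) < 2

  method <- "reml"
  fit <- NULL
  if (single_participant || noiseless) {
    warn(if (single_participant) {
      "Only one participant: falling back to ordinary least squares."
    } else {
      "Residual variance is essentially zero: using ordinary least squares."
    })
    method <- "ols"
    fit <- ols
  } else {
    fit <- suppressMessages(lmerTest::lmer(
      y ~ ac + fat + protein2 + fiber2 + (1 | participant_id),
      data = dat, REML = TRUE
    ))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warn("Participant variance collapsed to zero: refitting as OLS.")
      method <- "ols"
      fit <- ols
    }
  }

  if (method == "reml") {
    sm <- coef(summary(fit))   # Satterthwaite df from lmerTest
    est <- sm[, "Estimate"]
    se <- sm[, "Std. Error"]
    df <- sm[, "df"]
    p <- sm[, "Pr(>|t|)"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    participant_variance <- vc$vcov[vc$grp == "participant_id"]
    residual_variance <- vc$vcov[vc$grp == "Residual"]
  } else {
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    df <- rep(fit$df.residual, length(est))
    tstat <- est / se
    p <- 2 * stats::pt(-abs(tstat), df)
    p[!is.finite(tstat)] <- NA_real_
    participant_variance <- 0
    residual_variance <- sigma(fit)^2
  }
  term_names <- c("intercept", "carb", "fat", "protein2", "fiber2")
  names(est) <- names(se) <- names(df) <- names(p) <- term_names

  structure(
    list(
      coefficients = est,
      std_errors = se,
      df = df,
      p_values = p,
      participant_variance = participant_variance,
      residual_variance = residual_variance,
      iauc_scale = iauc_scale,
      method = method,
      n_records = nrow(dat),
      n_participants = nlevels(dat$participant_id),
      fit = fit
    ),
    class = "iauc_model"
  )
}

#' @export
print.iauc_model <- function(x, digits = 4, ...) {
  b <- x$coefficients
  cat(sprintf(
    "<iauc_model> (%s, %d records, %d participants; iAUC in units of %g mg·min/dL)\n",
    toupper(x$method), x$n_records, x$n_participants, x$iauc_scale
  ))
  cat(sprintf(
    "  iAUC = %.*g + %.*g·availCarb + %.*g·fat + %.*g·protein² + %.*g·fiber²\n",
    digits, b[["intercept"]], digits, b[["carb"]], digits, b[["fat"]],
    digits, b[["protein2"]], digits, b[["fiber2"]]
  ))
  invisible(x)
}

#' @rdname fit_iauc_model
#' @param x An `iauc_model`.
#' @param conf_level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.iauc_model <- function(x, conf_level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - conf_level) / 2, x$df)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(x$coefficients / x$std_errors),
    df = unname(x$df),
    p.value = unname(x$p_values),
    conf.low = unname(x$coefficients - tq * x$std_errors),
    conf.high = unname(x$coefficients + tq * x$std_errors)
  )
}

#' @rdname fit_iauc_model
#' @exportS3Method generics::glance
glance.iauc_model <- function(x, ...) {
  tibble::tibble(
    nobs = x$n_records,
    n_participants = x$n_participants,
    participant_variance = x$participant_variance,
    residual_variance = x$residual_variance,
    method = x$method
  )
}

#' Fit the GL-on-iAUC bridge regression
#'
#' Ordinary least squares of GL on iAUC (working scale), the linear map
#' later composed with the iAUC model to give the nutrition-label GL
#' formula. Fitted at record (participant x meal) level by default; a
#' meal-level option averages records per meal first.
#'
#' @param records Record table with finite `gl` and `iauc`.
#' @param level `"record"` (default) or `"meal"`.
#' @param iauc_scale mg·min/dL per working-scale unit.
#' @return An object of class `gl_bridge` with `alpha` (intercept) and
#'   `beta` (slope per working-scale iAUC unit).
#' @export
fit_gl_bridge <- function(records, level = c("record", "meal"),
                          iauc_scale = 100) {
  level <- match.arg(level)
  check_columns(records, c("gl", "iauc"), "record table")
  dat <- dplyr::filter(records, is.finite(.data$gl), is.finite(.data$iauc))
  if (level == "meal") {
    check_columns(dat, "meal_id", "record table")
    dat <- dplyr::summarise(dplyr::group_by(dat, .data$meal_id),
                            gl = mean(.data$gl), iauc = mean(.data$iauc),
                            .groups = "drop")
  }
  if (nrow(dat) < 3) {
    abort("Need at least 3 records with finite gl and iauc.",
          class = "glload_input_error")
  }
  x <- dat$iauc / iauc_scale
  if (stats::var(x) == 0) {
    abort("Zero variance in iauc: bridge regression is degenerate.",
          class = "glload_degenerate_regression")
  }
  fit <- lm(dat$gl ~ x)
  structure(
    list(alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
         level = level, iauc_scale = iauc_scale, n = nrow(dat), fit = fit),
    class = "gl_bridge"
  )
}

#' @export
print.gl_bridge <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<gl_bridge> GL = %.*g + %.*g · iAUC  (%s level, n = %d, iAUC in %g mg·min/dL units)\n",
    digits, x$alpha, digits, x$beta, x$level, x$n, x$iauc_scale
  ))
  invisible(x)
}

#' @rdname fit_gl_bridge
#' @param x A `gl_bridge`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gl_bridge <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_gl_bridge
#' @exportS3Method generics::glance
glance.gl_bridge <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma, nobs = x$n,
                 level = x$level)
}

#' Compose the GL prediction formula
#'
#' Substitutes the fitted iAUC linear predictor into the GL-on-iAUC
#' bridge: the composed intercept is `alpha + beta * intercept_iauc` and
#' each nutrient coefficient is `beta` times the corresponding iAUC
#' coefficient. Composition is done at full precision; rounding is a
#' display concern.
#'
#' @param iauc_model An [fit_iauc_model()] result (or a named coefficient
#'   vector as from [published_iauc_coefficients()]).
#' @param bridge A [fit_gl_bridge()] result (or a list with `alpha`,
#'   `beta`).
#' @return A [gl_formula()] object.
#' @export
compose_gl_formula <- function(iauc_model, bridge) {
  b <- if (inherits(iauc_model, "iauc_model")) iauc_model$coefficients
       else iauc_model
  gl_formula(
    intercept = bridge$alpha + bridge$beta * b[["intercept"]],
    coef_carb = bridge$beta * b[["carb"]],
    coef_fat = bridge$beta * b[["fat"]],
    coef_protein2 = bridge$beta * b[["protein2"]],
    coef_fiber2 = bridge$beta * b[["fiber2"]],
    version = "composed"
  )
}

#' Validate GL predictions against measured meal GL
#'
#' Regresses measured mean GL (y) on formula-predicted GL (x) across
#' meals, the standard measured-versus-predicted calibration check. A
#' slope of 1 and intercept of 0 indicate a perfectly calibrated formula.
#'
#' @param meal_summaries Output of [summarize_meals()] (needs `meal_id`,
#'   `gl_mean`).
#' @param formula A [gl_formula()].
#' @param meals Meal nutrient table used for prediction.
#' @return An object of class `gl_validation` with `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `n_meals` and the
#'   per-meal `data`.
#' @export
validate_predictions <- function(meal_summaries, formula, meals) {
  check_columns(meal_summaries, c("meal_id", "gl_mean"), "meal summary table")
  dat <- dplyr::inner_join(
    dplyr::select(meal_summaries, "meal_id", measured = "gl_mean"),
    meals, by = "meal_id"
  )
  if (nrow(dat) < 3) {
    abort("Need at least 3 meals to validate predictions.",
          class = "glload_input_error")
  }
  dat$predicted <- suppressWarnings(predict_gl(dat, formula))
  fit <- lm(measured ~ predicted, data = dat)
  s <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = s$r.squared,
      p_value = s$coefficients["predicted", "Pr(>|t|)"],
      n_meals = nrow(dat),
      data = dplyr::select(dat, "meal_id", "predicted", "measured"),
      fit = fit
    ),
    class = "gl_validation"
  )
}

#' @export
print.gl_validation <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<gl_validation> measured GL = %.*g + %.*g · predicted GL  (R² = %.*g, p = %.2g, %d meals)\n",
    digits, x$intercept, digits, x$slope, digits, x$r_squared, x$p_value,
    x$n_meals
  ))
  invisible(x)
}

#' @rdname validate_predictions
#' @param x A `gl_validation`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.gl_validation <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, p.value = x$p_value,
                 n_meals = x$n_meals)
}

#' @rdname validate_predictions
#' @exportS3Method generics::tidy
tidy.gl_validation <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}
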