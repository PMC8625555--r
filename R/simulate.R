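#' Simulation configuration for a synthetic feeding study
#'
#' Bundles and validates the parameters of the synthetic crossover design:
#' 34 participants split into 4 groups of 8-9, each group consuming 8 of
#' the 32 mixed meals, with duplicate sugar-solution references at each
#' carbohydrate tier (25/50/75 g) and glucose sampled at
#' 0/15/30/45/60/90/120 min.
#'
#' The generating truth for meal-level mean iAUC is the published linear
#' predictor on nutrients (see [iauc_linear_predictor()]), expressed on
#' the model's working scale of `iauc_scale` mg·min/dL per unit (100 by
#' default); participant heterogeneity enters as an additive random
#' intercept on the iAUC scale.
#'
#' @param n_participants,n_groups,meals_per_group Design sizes.
#' @param time_grid Measurement times in minutes, strictly increasing from 0.
#' @param baseline_mean,baseline_sd Fasting glucose distribution (mg/dL);
#'   defaults match the study cohort (92.5 +/- 5.4).
#' @param participant_sd SD of the per-participant random intercept on the
#'   iAUC scale (mg·min/dL).
#' @param residual_sd SD of test-level iAUC noise (mg·min/dL).
#' @param ref_iauc_by_tier Named vector: mean sugar-reference iAUC
#'   (mg·min/dL) per carbohydrate tier. Defaults are calibration choices
#'   placing simulated GI mid-range of the observed study GIs given the
#'   generating equation.
#' @param ref_cv Participant-level coefficient of variation of the
#'   reference iAUC (multiplicative).
#' @param ref_repeat_cv Additional repeat-level CV so duplicate references
#'   differ, as real duplicates do.
#' @param true_coefficients Named vector `(intercept, carb, fat, protein2,
#'   fiber2)` used as generating truth; defaults to the published fit.
#' @param iauc_scale mg·min/dL per unit of the model's working iAUC scale.
#' @param peak_time Minute at which simulated excursions peak.
#' @param seed Integer seed; the same config generates byte-identical
#'   tables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 34,
                       n_groups = 4,
                       meals_per_group = 8,
                       time_grid = default_time_grid(),
                       baseline_mean = 92.5,
                       baseline_sd = 5.4,
                       participant_sd = 400,
                       residual_sd = 500,
                       ref_iauc_by_tier = c("25" = 6600, "50" = 7600, "75" = 9000),
                       ref_cv = 0.10,
                       ref_repeat_cv = 0.05,
                       true_coefficients = published_iauc_coefficients(),
                       iauc_scale = 100,
                       peak_time = 30,
                       seed = 1L) {
  if (length(time_grid) < 2 || time_grid[1] != 0 || any(diff(time_grid) <= 0)) {
    abort("`time_grid` must be strictly increasing and start at 0.",
          class = "glload_config_error")
  }
  if (n_participants < n_groups) {
    abort("`n_participants` must be at least `n_groups`.",
          class = "glload_config_error")
  }
  sds <- c(baseline_sd, participant_sd, residual_sd, ref_cv, ref_repeat_cv)
  if (any(sds < 0)) {
    abort("All SDs / CVs must be non-negative.", class = "glload_config_error")
  }
  if (any(ref_iauc_by_tier <= 0)) {
    abort("`ref_iauc_by_tier` values must be positive.",
          class = "glload_config_error")
  }
  need <- c("intercept", "carb", "fat", "protein2", "fiber2")
  if (!all(need %in% names(true_coefficients))) {
    abort(sprintf("`true_coefficients` must be named: %s.",
                  paste(need, collapse = ", ")),
          class = "glload_config_error")
  }
  if (peak_time <= 0 || peak_time >= max(time_grid)) {
    abort("`peak_time` must lie strictly inside the grid span.",
          class = "glload_config_error")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_groups = as.integer(n_groups),
      meals_per_group = as.integer(meals_per_group),
      time_grid = time_grid,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      participant_sd = participant_sd, residual_sd = residual_sd,
      ref_iauc_by_tier = ref_iauc_by_tier,
      ref_cv = ref_cv, ref_repeat_cv = ref_repeat_cv,
      true_coefficients = true_coefficients[need],
      iauc_scale = iauc_scale,
      peak_time = peak_time,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Published iAUC model coefficients
#'
#' The fixed-effect coefficients of the published repeated-measures fit of
#' iAUC (working scale, units of 100 mg·min/dL) on nutrient composition:
#' intercept 37.05, +0.35 per g available carbohydrate, -0.18 per g fat,
#' -0.01 per g squared protein, -0.01 per g squared fiber.
#'
#' @return Named numeric vector.
#' @export
published_iauc_coefficients <- function() {
  c(intercept = 37.05, carb = 0.35, fat = -0.18,
    protein2 = -0.01, fiber2 = -0.01)
}

#' Linear predictor of the iAUC model
#'
#' Evaluates `intercept + b_carb * (carb - fiber) + b_fat * fat +
#' b_protein2 * protein^2 + b_fiber2 * fiber^2` for each meal, on the
#' model's working iAUC scale. Available (net) carbohydrate is total
#' carbohydrate minus fiber.
#'
#' @param meals Data frame with `carb_g`, `fiber_g`, `protein_g`, `fat_g`.
#' @param coefficients Named vector as in [published_iauc_coefficients()].
#' @return Numeric vector, one value per meal row.
#' @export
iauc_linear_predictor <- function(meals,
                                  coefficients = published_iauc_coefficients()) {
  check_columns(meals, c("carb_g", "fiber_g", "protein_g", "fat_g"), "meal table")
  ac <- meals$carb_g - meals$fiber_g
  unname(
    coefficients[["intercept"]] +
      coefficients[["carb"]] * ac +
      coefficients[["fat"]] * meals$fat_g +
      coefficients[["protein2"]] * meals$protein_g^2 +
      coefficients[["fiber2"]] * meals$fiber_g^2
  )
}

#' Meal table for simulation
#'
#' By default returns the packaged 32-meal ready-to-eat nutrient table
#' (see [rte_meals()]); in random mode draws label-style compositions per
#' tier instead, clamping fiber to total carbohydrate if the draw exceeds
#' it.
#'
#' @param config A [sim_config()].
#' @param random If `TRUE`, sample nutrient compositions rather than using
#'   the packaged table. Uses the current RNG state.
#' @return Tibble of meals: `meal_id`, `name`, `kcal`, `carb_g`,
#'   `fiber_g`, `sugars_g`, `protein_g`, `fat_g`, `tier_g`.
#' @export
simulate_meals <- function(config = sim_config(), random = FALSE) {
  n_meals <- config$n_groups * config$meals_per_group
  if (!random) {
    meals <- dplyr::select(
      rte_meals(), "meal_id", "name", "kcal", "carb_g", "fiber_g",
      "sugars_g", "protein_g", "fat_g", "tier_g"
    )
    return(head(meals, n_meals))
  }
  tiers <- as.numeric(names(config$ref_iauc_by_tier))
  tier_g <- sort(rep_len(tiers, n_meals))
  carb <- tier_g * stats::runif(n_meals, 0.9, 1.1)
  fiber <- stats::runif(n_meals, 0, 0.35 * carb)
  over <- fiber > carb
  if (any(over)) {
    warn(sprintf("%d fiber draw(s) exceeded total carbohydrate; clamped.",
                 sum(over)))
    fiber[over] <- carb[over]
  }
  protein <- stats::runif(n_meals, 1, 23)
  fat <- stats::runif(n_meals, 0, 24)
  sugars <- stats::runif(n_meals, 0, 0.4 * carb)
  tibble::tibble(
    meal_id = seq_len(n_meals),
    name = sprintf("synthetic meal %02d", seq_len(n_meals)),
    kcal = round(4 * (carb + protein) + 9 * fat),
    carb_g = round(carb, 1), fiber_g = round(fiber, 1),
    sugars_g = round(sugars, 1), protein_g = round(protein, 1),
    fat_g = round(fat, 1), tier_g = tier_g
  )
}

#' Draw target iAUC values for meal tests
#'
#' The generating model: target iAUC (mg·min/dL) is
#' `iauc_scale * linear_predictor(meal) + random_intercept + noise`, with
#' `noise ~ Normal(0, residual_sd^2)`, truncated at zero. Truncation
#' events are reported via a message (rare at default parameters).
#'
#' @param meals Meal rows (recycled against `random_intercept`).
#' @param random_intercept Per-test participant random intercept(s) on the
#'   iAUC scale (mg·min/dL).
#' @param config A [sim_config()].
#' @return Numeric vector of non-negative iAUC targets (mg·min/dL). Uses
#'   the current RNG state.
#' @export
target_iauc <- function(meals, random_intercept = 0, config = sim_config()) {
  lp <- config$iauc_scale * iauc_linear_predictor(meals, config$true_coefficients)
  n <- max(length(lp), length(random_intercept))
  lp <- rep_len(lp, n)
  ri <- rep_len(random_intercept, n)
  eps <- if (config$residual_sd > 0) rnorm(n, 0, config$residual_sd) else 0
  raw <- lp + ri + eps
  truncated <- raw < 0
  if (any(truncated)) {
    rlang::inform(sprintf("target_iauc(): %d draw(s) truncated at zero.",
                          sum(truncated)))
  }
  pmax(raw, 0)
}

# unit-amplitude excursion shape and its trapezoidal area on the grid
excursion_shape <- function(time_grid, peak_time) {
  s <- (time_grid / peak_time) * exp(1 - time_grid / peak_time)
  w <- sum(diff(time_grid) * (s[-1] + s[-length(s)]) / 2)
  list(shape = s, area = w)
}

#' Simulate a single glucose curve with a prescribed iAUC
#'
#' Generates a single-peak excursion above baseline,
#' `delta(t) = A * (t / peak_time) * exp(1 - t / peak_time)`, with the
#' amplitude `A` solved so the trapezoidal iAUC of the 7-point curve
#' equals `iauc_target` exactly (the shape never dips below baseline, so
#' the incremental and trapezoidal areas coincide). A zero target yields a
#' flat curve at baseline.
#'
#' @param iauc_target Desired iAUC (mg·min/dL), non-negative.
#' @param baseline Fasting glucose (mg/dL), positive.
#' @param peak_time Minute of the excursion maximum, inside the grid span.
#' @param time_grid Measurement times.
#' @return Numeric vector of glucose readings (mg/dL) on `time_grid`.
#' @examples
#' g <- simulate_glucose_curve(2000, baseline = 90)
#' incremental_auc(default_time_grid(), g)
#' @export
simulate_glucose_curve <- function(iauc_target, baseline, peak_time = 30,
                                   time_grid = default_time_grid()) {
  if (iauc_target < 0) abort("`iauc_target` must be non-negative.",
                             class = "glload_input_error")
  if (baseline <= 0) abort("`baseline` must be positive.",
                           class = "glload_input_error")
  if (peak_time <= 0 || peak_time >= max(time_grid)) {
    abort("`peak_time` must lie inside the grid span.",
          class = "glload_input_error")
  }
  ex <- excursion_shape(time_grid, peak_time)
  baseline + (iauc_target / ex$area) * ex$shape
}

#' Simulate a full synthetic feeding study
#'
#' Assembles a complete synthetic study: participants with fasting
#' baselines and random intercepts, the meal table, duplicate
#' sugar-solution reference curves at each tier for every participant,
#' and one curve per assigned meal with iAUC drawn from the generating
#' model. The output is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param random_meals Passed to [simulate_meals()].
#' @return A list of class `gl_study` with elements `config`,
#'   `participants`, `meals`, `curves` (wide tibble, one row per test) and
#'   `truth` (generating parameters, for recovery checks).
#' @export
simulate_study <- function(config = sim_config(), random_meals = FALSE) {
  set.seed(config$seed)
  n <- config$n_participants
  tg <- config$time_grid
  tc <- time_cols(tg)

  # groups of size ceiling then floor: 34 over 4 -> 9,9,8,8
  base_size <- n %/% config$n_groups
  extra <- n %% config$n_groups
  sizes <- rep(base_size, config$n_groups) + rep(c(1, 0), c(extra, config$n_groups - extra))
  participants <- tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    group = rep(seq_len(config$n_groups), sizes),
    baseline_glucose = pmax(rnorm(n, config$baseline_mean, config$baseline_sd), 50),
    random_intercept = if (config$participant_sd > 0)
      rnorm(n, 0, config$participant_sd) else rep(0, n)
  )

  meals <- simulate_meals(config, random = random_meals)
  meals$sim_group <- rep(seq_len(config$n_groups), each = config$meals_per_group)

  tiers <- as.numeric(names(config$ref_iauc_by_tier))
  n_rep <- 2L

  # reference tests: participant-level multiplicative noise shared by the
  # duplicates, plus a small repeat-level component
  ref_design <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    tier_g = tiers,
    rep = seq_len(n_rep)
  )
  part_mult <- stats::setNames(
    matrix(1 + rnorm(n * length(tiers), 0, config$ref_cv), nrow = n,
           dimnames = list(participants$participant_id, as.character(tiers))),
    NULL
  )
  rep_mult <- 1 + rnorm(nrow(ref_design), 0, config$ref_repeat_cv)
  tier_mean <- config$ref_iauc_by_tier[as.character(ref_design$tier_g)]
  pm <- part_mult[cbind(
    match(ref_design$participant_id, participants$participant_id),
    match(as.character(ref_design$tier_g), as.character(tiers))
  )]
  ref_design$target <- pmax(tier_mean * pm * rep_mult, 0)

  # meal tests: each participant eats their group's meals once
  meal_design <- dplyr::inner_join(
    dplyr::select(participants, "participant_id", "group", "random_intercept"),
    dplyr::select(meals, "meal_id", "tier_g", "carb_g", "fiber_g",
                  "protein_g", "fat_g", sim_group = "sim_group"),
    by = c(group = "sim_group"), relationship = "many-to-many"
  )
  meal_design$target <- target_iauc(
    meal_design[, c("carb_g", "fiber_g", "protein_g", "fat_g")],
    meal_design$random_intercept, config
  )

  ex <- excursion_shape(tg, config$peak_time)
  curve_matrix <- function(targets, baselines) {
    outer(targets / ex$area, ex$shape) + baselines
  }
  bl <- stats::setNames(participants$baseline_glucose,
                        participants$participant_id)

  ref_g <- curve_matrix(ref_design$target, bl[ref_design$participant_id])
  colnames(ref_g) <- tc
  ref_curves <- dplyr::bind_cols(
    tibble::tibble(
      participant_id = ref_design$participant_id,
      group = participants$group[match(ref_design$participant_id,
                                       participants$participant_id)],
      test_type = "reference",
      meal_id = NA_integer_,
      tier_g = ref_design$tier_g,
      rep = ref_design$rep
    ),
    tibble::as_tibble(ref_g)
  )

  meal_g <- curve_matrix(meal_design$target, bl[meal_design$participant_id])
  colnames(meal_g) <- tc
  meal_curves <- dplyr::bind_cols(
    tibble::tibble(
      participant_id = meal_design$participant_id,
      group = meal_design$group,
      test_type = "meal",
      meal_id = meal_design$meal_id,
      tier_g = meal_design$tier_g,
      rep = 1L
    ),
    tibble::as_tibble(meal_g)
  )

  curves <- dplyr::arrange(
    dplyr::bind_rows(ref_curves, meal_curves),
    .data$participant_id, .data$test_type, .data$tier_g, .data$meal_id, .data$rep
  )

  structure(
    list(
      config = config,
      participants = participants,
      meals = dplyr::select(meals, -"sim_group"),
      curves = curves,
      truth = list(
        coefficients = config$true_coefficients,
        iauc_scale = config$iauc_scale,
        participant_sd = config$participant_sd,
        residual_sd = config$residual_sd,
        ref_iauc_by_tier = config$ref_iauc_by_tier
      )
    ),
    class = "gl_study"
  )
}

#' @export
print.gl_study <- function(x, ...) {
  cat(sprintf(
    "<gl_study> %d participants in %d groups, %d meals, %d curves (seed %d)\n",
    nrow(x$participants), x$config$n_groups, nrow(x$meals), nrow(x$curves),
    x$config$seed
  ))
  invisible(x)
}
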