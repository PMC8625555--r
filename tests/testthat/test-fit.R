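noiseless_records <- function(n_participants = 6, coefs = published_iauc_coefficients()) {
  meals <- dplyr::select(rte_meals(), "meal_id", "carb_g", "fiber_g",
                         "protein_g", "fat_g")
  rec <- tidyr::expand_grid(participant_id = sprintf("P%02d", seq_len(n_participants)),
                            meal_id = meals$meal_id)
  rec <- dplyr::left_join(rec, meals, by = "meal_id")
  rec$iauc <- 100 * iauc_linear_predictor(rec, coefs)
  rec
}

test_that("the iAUC model recovers generating coefficients from noiseless data", {
  rec <- noiseless_records()
  expect_warning(fit <- fit_iauc_model(rec), "zero")
  expect_equal(fit$method, "ols")
  expect_equal(unname(fit$coefficients),
               unname(published_iauc_coefficients()), tolerance = 1e-9)
  expect_equal(unname(fit$p_values[["carb"]]), 0, tolerance = 1e-12)
})

test_that("the mixed model recovers coefficients and variance components", {
  withr::local_seed(31)
  rec <- noiseless_records(n_participants = 30)
  b <- rnorm(30, 0, 4)   # participant intercepts, working scale units
  rec$iauc <- rec$iauc + 100 * (b[as.integer(factor(rec$participant_id))] +
                                  rnorm(nrow(rec), 0, 3))
  fit <- fit_iauc_model(rec)
  expect_equal(fit$method, "reml")
  expect_equal(unname(fit$coefficients[["carb"]]), 0.35, tolerance = 0.15)
  expect_equal(sqrt(fit$participant_variance), 4, tolerance = 0.5)
  expect_equal(sqrt(fit$residual_variance), 3, tolerance = 0.1)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "carb", "fat", "protein2", "fiber2"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  expect_equal(glance(fit)$n_participants, 30)
})

test_that("degenerate designs fall back or fail loudly", {
  rec <- noiseless_records(n_participants = 1)
  expect_warning(fit <- fit_iauc_model(rec))
  expect_equal(fit$method, "ols")

  same_meal <- noiseless_records()
  same_meal$carb_g <- 50; same_meal$fiber_g <- 5
  same_meal$protein_g <- 10; same_meal$fat_g <- 8
  expect_error(fit_iauc_model(same_meal), class = "glload_singular_design")
})

test_that("estimates are invariant to record order", {
  withr::local_seed(8)
  rec <- noiseless_records(n_participants = 12)
  b <- rnorm(12, 0, 400)
  rec$iauc <- rec$iauc + b[as.integer(factor(rec$participant_id))] +
    rnorm(nrow(rec), 0, 300)
  f1 <- fit_iauc_model(rec)
  f2 <- fit_iauc_model(rec[sample(nrow(rec)), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  rec$gl <- rec$iauc / 120
  b1 <- fit_gl_bridge(rec)
  b2 <- fit_gl_bridge(rec[sample(nrow(rec)), ])
  expect_equal(c(b1$alpha, b1$beta), c(b2$alpha, b2$beta), tolerance = 1e-10)
})

test_that("the GL bridge recovers an exact linear relation and edge cases", {
  rec <- tibble::tibble(iauc = c(1000, 2000, 3000, 4500),
                        gl = -22.07 + 1.12 * c(10, 20, 30, 45))
  br <- fit_gl_bridge(rec)
  expect_equal(br$alpha, -22.07, tolerance = 1e-10)
  expect_equal(br$beta, 1.12, tolerance = 1e-10)

  const <- tibble::tibble(iauc = c(1000, 2000, 3000), gl = 7)
  bc <- fit_gl_bridge(const)
  expect_equal(bc$beta, 0, tolerance = 1e-12)
  expect_equal(bc$alpha, 7, tolerance = 1e-12)

  expect_error(fit_gl_bridge(rec[1:2, ]), class = "glload_input_error")
  expect_error(fit_gl_bridge(tibble::tibble(iauc = rep(2000, 5), gl = 1:5)),
               class = "glload_degenerate_regression")
})

test_that("the bridge OLS matches the closed-form normal equations", {
  withr::local_seed(14)
  for (i in 1:10) {
    n <- 50
    x <- stats::runif(n, 500, 6000)
    y <- stats::rnorm(n, 5 + 0.01 * x, 3)
    br <- fit_gl_bridge(tibble::tibble(iauc = x, gl = y), iauc_scale = 1)
    beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    alpha_hat <- mean(y) - beta_hat * mean(x)
    expect_equal(br$beta, beta_hat, tolerance = 1e-10)
    expect_equal(br$alpha, alpha_hat, tolerance = 1e-10)
  }
})

test_that("meal-level bridge averages records per meal first", {
  rec <- tibble::tibble(
    meal_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    iauc = c(1000, 2000, 3000, 4000, 5000, 6000),
    gl = c(5, 15, 20, 30, 35, 45)
  )
  bm <- fit_gl_bridge(rec, level = "meal")
  expect_equal(bm$n, 3)
  # meal means (15, 35, 55; 10, 25, 40) lie exactly on gl = -1.25 + 0.75x
  expect_equal(bm$beta, 0.75, tolerance = 1e-10)
  expect_equal(bm$alpha, -1.25, tolerance = 1e-10)
})

test_that("composition merges the two fits at full precision", {
  iauc_fit <- list(coefficients = published_iauc_coefficients())
  class(iauc_fit) <- "iauc_model"
  identity_bridge <- list(alpha = 0, beta = 1)
  f <- compose_gl_formula(iauc_fit, identity_bridge)
  expect_equal(f$intercept, 37.05)
  expect_equal(f$coef_carb, 0.35)
  expect_equal(f$coef_fiber2, -0.01)

  printed_bridge <- list(alpha = -22.07, beta = 1.12)
  g <- compose_gl_formula(iauc_fit, printed_bridge)
  expect_equal(g$intercept, -22.07 + 1.12 * 37.05)   # 19.426
  expect_equal(g$intercept, 19.426)
  expect_equal(g$coef_carb, 0.392)
  expect_equal(g$coef_fat, -0.2016)
  expect_equal(g$coef_protein2, -0.0112)
  expect_equal(g$coef_fiber2, -0.0112)

  zero_bridge <- list(alpha = 3, beta = 0)
  z <- compose_gl_formula(iauc_fit, zero_bridge)
  expect_equal(z$intercept, 3)
  expect_equal(c(z$coef_carb, z$coef_fat, z$coef_protein2, z$coef_fiber2),
               rep(0, 4))
})

test_that("predicting through the composed formula equals bridging the linear predictor", {
  withr::local_seed(2)
  iauc_fit <- list(coefficients = published_iauc_coefficients())
  class(iauc_fit) <- "iauc_model"
  bridge <- list(alpha = -22.07, beta = 1.12)
  f <- compose_gl_formula(iauc_fit, bridge)
  for (i in 1:100) {
    carb <- stats::runif(1, 10, 110)
    meal <- tibble::tibble(carb_g = carb,
                           fiber_g = stats::runif(1, 0, min(16, carb)),
                           protein_g = stats::runif(1, 0, 25),
                           fat_g = stats::runif(1, 0, 25))
    via_formula <- suppressWarnings(predict_gl(meal, f))
    via_bridge <- bridge$alpha + bridge$beta * iauc_linear_predictor(meal)
    expect_equal(via_formula, via_bridge, tolerance = 1e-12)
  }
})

test_that("validation regression reports slope, intercept and R²", {
  meals <- dplyr::select(rte_meals(), "meal_id", "carb_g", "fiber_g",
                         "protein_g", "fat_g")
  pred <- suppressWarnings(predict_gl(meals))
  perfect <- tibble::tibble(meal_id = meals$meal_id, gl_mean = pred)
  v <- validate_predictions(perfect, published_gl_formula(), meals)
  expect_equal(v$slope, 1, tolerance = 1e-9)
  expect_equal(v$intercept, 0, tolerance = 1e-7)
  expect_equal(v$r_squared, 1, tolerance = 1e-9)

  double <- tibble::tibble(meal_id = meals$meal_id, gl_mean = 2 * pred)
  v2 <- validate_predictions(double, published_gl_formula(), meals)
  expect_equal(v2$slope, 2, tolerance = 1e-9)
  expect_equal(v2$r_squared, 1, tolerance = 1e-9)

  expect_error(validate_predictions(perfect[1:2, ], published_gl_formula(), meals),
               class = "glload_input_error")
  expect_s3_class(autoplot(v), "ggplot")
})
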