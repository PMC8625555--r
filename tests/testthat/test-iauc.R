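test_that("incremental_auc matches hand-computed piecewise-linear areas", {
  # all readings at or above baseline: plain trapezoids
  expect_equal(
    incremental_auc(grid7, c(90, 110, 120, 110, 100, 95, 90)),
    1425
  )
  # dips below baseline: only the above-baseline triangles count
  expect_equal(
    incremental_auc(grid7, c(90, 100, 85, 95, 90, 90, 90)),
    181.25
  )
  # flat at baseline
  expect_equal(incremental_auc(grid7, rep(92, 7)), 0)
  # entirely below baseline after t0
  expect_equal(incremental_auc(grid7, c(100, 95, 90, 92, 95, 99, 100)), 0)
})

test_that("incremental_auc agrees with a fine-grid numerical oracle", {
  withr::local_seed(42)
  for (i in 1:200) {
    g <- random_curve()
    exact <- incremental_auc(grid7, g)
    approx <- iauc_oracle(grid7, g)
    expect_lt(abs(exact - approx) / max(approx, 1), 1e-6)
  }
})

test_that("iAUC is equivariant to scaling increments and invariant to collinear points", {
  withr::local_seed(7)
  for (i in 1:25) {
    g <- random_curve()
    base <- incremental_auc(grid7, g)
    # scale all increments by c > 0
    cc <- stats::runif(1, 0.2, 5)
    expect_equal(incremental_auc(grid7, g[1] + cc * (g - g[1])), cc * base)
    # insert collinear midpoints: integral unchanged
    mid_t <- head(grid7, -1) + diff(grid7) / 2
    tt <- sort(c(grid7, mid_t))
    gg <- stats::approx(grid7, g, xout = tt)$y
    expect_equal(incremental_auc(tt, gg), base)
  }
})

test_that("incremental_auc rejects malformed input", {
  expect_error(incremental_auc(0, 90), class = "glload_input_error")
  expect_error(incremental_auc(c(0, 15, 15), c(90, 95, 96)),
               class = "glload_input_error")
  expect_error(incremental_auc(c(0, 15), c(90, NA)),
               class = "glload_input_error")
})

test_that("reference_iauc averages a participant's duplicate sugar tests", {
  curves <- dplyr::bind_rows(
    make_curve_row("P01", "reference", NA, 25, 1,
                   simulate_glucose_curve(2800, 90)),
    make_curve_row("P01", "reference", NA, 25, 2,
                   simulate_glucose_curve(3000, 90)),
    make_curve_row("P02", "reference", NA, 25, 1,
                   simulate_glucose_curve(2500, 95))
  )
  expect_equal(reference_iauc(curves, "P01", 25), 2900)
  expect_warning(one <- reference_iauc(curves, "P02", 25), "Single reference")
  expect_equal(one, 2500)
  expect_error(reference_iauc(curves, "P03", 25),
               class = "glload_missing_reference")
  expect_error(reference_iauc(curves, "P01", 50),
               class = "glload_missing_reference")
})

test_that("compute_gi and compute_gl follow their defining ratios", {
  expect_equal(compute_gi(2000, 2000), 100)
  expect_equal(compute_gi(500, 2000), 25)
  expect_equal(compute_gi(0, 2000), 0)
  expect_error(compute_gi(500, 0), class = "glload_degenerate_reference")

  expect_equal(compute_gl(53, 26, 2), 12.72)
  expect_equal(round_half_away(compute_gl(53, 26, 2)), 13)
  expect_equal(compute_gl(40, 52, 7), 18)
  expect_equal(compute_gl(70, 30, 30), 0)   # fiber == carb
  expect_error(compute_gl(50, 20, 25), class = "glload_input_error")
})

test_that("glycemic_records derives iAUC, GI and GL per participant-meal", {
  curves <- dplyr::bind_rows(
    make_curve_row("P01", "reference", NA, 25, 1, simulate_glucose_curve(1900, 90)),
    make_curve_row("P01", "reference", NA, 25, 2, simulate_glucose_curve(2100, 90)),
    make_curve_row("P01", "meal", 1L, 25, 1, simulate_glucose_curve(1000, 90))
  )
  meals <- tibble::tibble(meal_id = 1L, carb_g = 26, fiber_g = 2,
                          protein_g = 5, fat_g = 10)
  rec <- glycemic_records(curves, meals)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$iauc, 1000, tolerance = 1e-9)
  expect_equal(rec$ref_iauc, 2000, tolerance = 1e-9)
  expect_equal(rec$gi, 50, tolerance = 1e-9)
  expect_equal(rec$gl, 50 * 24 / 100, tolerance = 1e-9)
  # stored gl is exactly gi * available carb / 100
  expect_equal(rec$gl, rec$gi * (rec$carb_g - rec$fiber_g) / 100)

  expect_error(
    glycemic_records(
      dplyr::mutate(curves, meal_id = dplyr::if_else(test_type == "meal", 99L, meal_id)),
      meals
    ),
    class = "glload_join_error"
  )
})

test_that("summarize_meals computes sample SDs over retained records", {
  rec <- tibble::tibble(
    participant_id = c("P01", "P02"), meal_id = 1L, tier_g = 25,
    iauc = c(10, 20), ref_iauc = 100, gi = c(10, 20), gl = c(10, 20)
  )
  s <- summarize_meals(rec)
  expect_equal(s$gl_mean, 15)
  expect_equal(s$gl_sd, sd(c(10, 20)))
  expect_equal(s$gl_sd, 7.0710678, tolerance = 1e-6)
  expect_equal(s$n, 2)

  single <- summarize_meals(rec[1, ])
  expect_equal(single$gl_sd, 0)
  expect_true(single$single_record)

  rec$excluded <- c(FALSE, TRUE)
  expect_equal(summarize_meals(rec)$n, 1)
  rec$excluded <- TRUE
  expect_error(summarize_meals(rec), class = "glload_empty_summary")
})

test_that("round_half_away rounds ties away from zero", {
  expect_equal(round_half_away(c(12.5, 13.5, -12.5, 0.5)), c(13, 14, -13, 1))
  expect_equal(round_half_away(1.25, 1), 1.3)
})
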