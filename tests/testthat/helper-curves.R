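# shared fixtures built in code

grid7 <- c(0, 15, 30, 45, 60, 90, 120)

make_curve_row <- function(participant_id = "P01", test_type = "meal",
                           meal_id = 1L, tier_g = 25, rep = 1L,
                           glucose = rep(90, 7), group = 1L) {
  row <- tibble::tibble(participant_id = participant_id, group = group,
                        test_type = test_type, meal_id = meal_id,
                        tier_g = tier_g, rep = rep)
  g <- tibble::as_tibble(as.list(stats::setNames(glucose, paste0("t", grid7))))
  dplyr::bind_cols(row, g)
}

# independent fine-grid oracle for the incremental AUC: numerically
# integrate max(interpolated glucose - baseline, 0) on a 0.001-min grid
iauc_oracle <- function(times, glucose, step = 0.001) {
  tt <- seq(min(times), max(times), by = step)
  g <- stats::approx(times, glucose, xout = tt)$y
  inc <- pmax(g - glucose[1], 0)
  sum((inc[-1] + inc[-length(inc)]) / 2) * step
}

random_curve <- function(baseline = 90, sd = 20) {
  c(baseline, baseline + stats::rnorm(6, 5, sd))
}

tiny_config <- function(...) {
  sim_config(n_participants = 6, n_groups = 2, meals_per_group = 4, ...)
}
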