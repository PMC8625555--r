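#' Plot glucose curves
#'
#' Spaghetti plot of postprandial glucose trajectories, one line per
#' test, faceted by carbohydrate tier and coloured by test type.
#'
#' @param curves Wide curve table.
#' @param time_grid Measurement times matching the `t*` columns.
#' @param max_curves Downsample to at most this many curves (plots of a
#'   full study are unreadable otherwise).
#' @return A ggplot object.
#' @export
plot_glucose_curves <- function(curves, time_grid = default_time_grid(),
                                max_curves = 100) {
  check_columns(curves, c("participant_id", "test_type", "tier_g",
                          time_cols(time_grid)), "curve table")
  curves <- tibble::as_tibble(curves)
  curves$curve_id <- seq_len(nrow(curves))
  if (nrow(curves) > max_curves) {
    curves <- curves[sort(sample(nrow(curves), max_curves)), ]
  }
  long <- tidyr::pivot_longer(
    curves, dplyr::all_of(time_cols(time_grid)),
    names_to = "time", values_to = "glucose"
  )
  long$time <- as.numeric(sub("^t", "", long$time))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time, y = .data$glucose,
    group = .data$curve_id, colour = .data$test_type
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tier_g), labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time after first bite (min)", y = "Glucose (mg/dL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Measured-versus-predicted GL plot
#'
#' Scatter of measured mean GL against formula-predicted GL per meal,
#' with the fitted calibration line and the identity line for reference.
#'
#' @param object A [validate_predictions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gl_validation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$predicted, y = .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Predicted GL", y = "Measured mean GL",
      title = sprintf("measured = %.2f + %.2f x predicted (R² = %.2f, n = %d)",
                      object$intercept, object$slope, object$r_squared,
                      object$n_meals)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.gl_validation <- function(x, ...) print(autoplot.gl_validation(x, ...))
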