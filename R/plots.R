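## Diagnostic ggplot2 figures -------------------------------------------------

#' Plot moisture-ratio decay curves
#'
#' @param curves Long curves tibble (see [simulate_experiment()]).
#' @return A ggplot of MR vs drying time, one line per condition.
#' @export
plot_drying_curves <- function(curves) {
  check_columns(curves, c("condition_id", "t_s", "mr"))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$t_s / 60, y = .data$mr,
                               colour = .data$condition_id)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Drying time (min)", y = "Moisture ratio MR",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.thin_layer_fit <- function(object, ...) {
  grid <- tibble::tibble(
    t_s = seq(min(object$data$t_s), max(object$data$t_s), length.out = 200))
  grid$mr <- evaluate_model(object$model, object$parameters, grid$t_s)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_s / 60,
                                            y = .data$mr)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Drying time (min)", y = "Moisture ratio MR",
                  title = sprintf("%s fit (R2 = %.4f)", object$label,
                                  object$stats$r2)) +
    ggplot2::theme_minimal()
}

#' Arrhenius diagnostic plot
#'
#' ln(Deff) against 1/T with the fitted regression line per
#' (velocity, intensity) group.
#'
#' @param deff_tbl Output of [estimate_deff_all()] with condition columns.
#' @return A ggplot.
#' @export
plot_arrhenius <- function(deff_tbl) {
  check_columns(deff_tbl, c("temperature_c", "deff_m2s"))
  tbl <- dplyr::mutate(
    deff_tbl,
    inv_t = 1 / celsius_to_kelvin(.data$temperature_c),
    group = if ("velocity_ms" %in% names(deff_tbl)) {
      sprintf("V=%.1f, IR=%.0f", .data$velocity_ms, .data$intensity_wm2)
    } else "all"
  )
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$inv_t,
                                    y = log(.data$deff_m2s),
                                    colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "1 / T (1/K)", y = "ln Deff", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trained_mlp <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch,
                                               y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "Training MSE (normalized scale)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.som_fit <- function(object, ...) {
  ggplot2::ggplot(object$unit_coords,
                  ggplot2::aes(x = .data$gx, y = .data$gy,
                               fill = factor(.data$cluster))) +
    ggplot2::geom_tile(colour = "grey90", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Cluster") +
    ggplot2::theme_minimal()
}
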