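#' Build the factorial grid of drying conditions
#'
#' Constructs the full factorial crossing of drying-air temperature, airflow
#' velocity and infrared intensity. The default levels are the 3 x 3 x 3
#' experimental grid used throughout the package: 40/50/60 degC,
#' 0.3/0.7/1.0 m/s and 1500/3500/5500 W/m2. Ordering is deterministic:
#' temperature varies slowest, velocity next, intensity fastest.
#'
#' @param temperature_c Numeric vector of air temperatures (degC), all > 0.
#' @param velocity_ms Numeric vector of airflow velocities (m/s), all > 0.
#' @param intensity_wm2 Numeric vector of infrared intensities (W/m2), all > 0.
#'
#' @return A tibble with one row per condition: `condition_id`,
#'   `temperature_c`, `velocity_ms`, `intensity_wm2`.
#' @examples
#' make_conditions_grid()            # 27 conditions
#' make_conditions_grid(50, 0.7, 3500)  # a single condition
#' @export
make_conditions_grid <- function(temperature_c = c(40, 50, 60),
                                 velocity_ms = c(0.3, 0.7, 1.0),
                                 intensity_wm2 = c(1500, 3500, 5500)) {
  stopifnot(is.numeric(temperature_c), is.numeric(velocity_ms),
            is.numeric(intensity_wm2))
  if (any(temperature_c <= 0) || any(velocity_ms <= 0) ||
      any(intensity_wm2 <= 0)) {
    abort("All condition levels must be strictly positive.",
          class = "drykin_error_domain")
  }
  grid <- tidyr::expand_grid(
    temperature_c = temperature_c,
    velocity_ms = velocity_ms,
    intensity_wm2 = intensity_wm2
  )
  dplyr::mutate(
    grid,
    condition_id = sprintf("T%02.0f_V%03.1f_IR%04.0f",
                           .data$temperature_c, .data$velocity_ms,
                           .data$intensity_wm2),
    .before = 1
  )
}

## Map a factor linearly onto the coded interval [-1, 1] over its level range.
## A factor with a single level codes to 0.
code_factor <- function(x, lo = min(x), hi = max(x)) {
  if (hi == lo) return(rep(0, length(x)))
  2 * (x - lo) / (hi - lo) - 1
}

#' Add coded process variables to a conditions table
#'
#' Maps each of temperature, velocity and intensity linearly onto `[-1, 1]`
#' over its observed range (the coded-variable convention used for quality
#' response surfaces).
#'
#' @param conditions A conditions tibble (see [make_conditions_grid()]).
#' @return The input with `t_coded`, `v_coded`, `ir_coded` columns appended.
#' @export
code_conditions <- function(conditions) {
  check_columns(conditions, c("temperature_c", "velocity_ms", "intensity_wm2"))
  dplyr::mutate(
    conditions,
    t_coded = code_factor(.data$temperature_c),
    v_coded = code_factor(.data$velocity_ms),
    ir_coded = code_factor(.data$intensity_wm2)
  )
}

## R-squared of an lm fit without summary.lm (which warns on exact fits).
r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

check_columns <- function(data, cols, arg = deparse(substitute(data))) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(
      sprintf("`%s` is missing required column(s): %s", arg,
              paste0("`", missing, "`", collapse = ", ")),
      class = "drykin_error_schema"
    )
  }
  invisible(data)
}
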