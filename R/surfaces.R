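## Response-surface correlations of process variables -------------------------

#' Construct a linear drying-time surface from known coefficients
#'
#' A linear correlation `time = c0 + c_ir * IR + c_v * V + c_t * T` of drying
#' time against infrared intensity, airflow velocity and air temperature.
#' Coefficient magnitudes of published correlations of this form imply IR in
#' kW/m2 (an intensity in W/m2 would dwarf the intercept), so that is the
#' default unit metadata; temperature enters in degC.
#'
#' @param intercept,coef_ir,coef_v,coef_t Surface coefficients (signs folded
#'   into the coefficients).
#' @param units Named list of predictor units metadata.
#' @param r2 Optional coefficient of determination of the fit that produced
#'   the coefficients.
#' @return A `linear_surface` object.
#' @examples
#' s <- linear_surface(616.12, -283.7, 50.21, -5.08)
#' evaluate_linear_surface(s, ir = 0, v = 0, t = 0) # the intercept
#' @export
linear_surface <- function(intercept, coef_ir, coef_v, coef_t,
                           units = list(ir = "kW/m2", v = "m/s", t = "degC",
                                        response = "min"),
                           r2 = NA_real_) {
  cf <- c(intercept = intercept, coef_ir = coef_ir, coef_v = coef_v,
          coef_t = coef_t)
  if (any(!is.finite(cf))) {
    abort("Surface coefficients must be finite.",
          class = "drykin_error_domain")
  }
  structure(list(coefficients = cf, units = units, r2 = r2),
            class = "linear_surface")
}

#' Fit a linear drying-time surface by ordinary least squares
#'
#' @param data Tibble with the response column plus `ir`, `v`, `t` predictor
#'   columns (units per `units`).
#' @param response Name of the response column (drying time).
#' @param units Predictor unit metadata stored with the surface.
#' @return A `linear_surface` with fitted coefficients and r2.
#' @export
fit_linear_surface <- function(data, response = "drying_time_min",
                               units = list(ir = "kW/m2", v = "m/s",
                                            t = "degC", response = "min")) {
  check_columns(data, c(response, "ir", "v", "t"))
  if (nrow(data) < 5) {
    abort("Need >= 5 conditions to fit the linear surface.",
          class = "drykin_error_domain")
  }
  X <- cbind(1, data$ir, data$v, data$t)
  if (qr(X)$rank < 4) {
    abort("Rank-deficient design: predictors must span >= 2 levels each.",
          class = "drykin_error_singular")
  }
  y <- data[[response]]
  fit <- lm(y ~ ir + v + t, data = data)
  cf <- coef(fit)
  linear_surface(cf[[1]], cf[["ir"]], cf[["v"]], cf[["t"]], units = units,
                 r2 = r_squared(fit, y))
}

#' Evaluate a linear surface
#'
#' @param surface A `linear_surface`.
#' @param ir,v,t Predictor values in the surface's units.
#' @return Predicted response, vectorised. Negative predictions trigger a
#'   warning (non-physical for a drying time, usually a unit mismatch).
#' @export
evaluate_linear_surface <- function(surface, ir, v, t) {
  stopifnot(inherits(surface, "linear_surface"))
  cf <- surface$coefficients
  out <- cf[["intercept"]] + cf[["coef_ir"]] * ir + cf[["coef_v"]] * v +
    cf[["coef_t"]] * t
  if (any(out < 0)) {
    warn(sprintf(
      "Negative predicted response; check predictor units (surface expects IR in %s).",
      surface$units$ir %||% "kW/m2"))
  }
  out
}

#' @export
print.linear_surface <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<linear_surface> y = %.4g + %.4g*IR + %.4g*V + %.4g*T  (IR in %s)\n",
              cf[["intercept"]], cf[["coef_ir"]], cf[["coef_v"]],
              cf[["coef_t"]], x$units$ir %||% "?"))
  if (is.finite(x$r2)) cat(sprintf("  r2 = %.3f\n", x$r2))
  invisible(x)
}

#' @export
tidy.linear_surface <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.linear_surface <- function(x, ...) tibble::tibble(r2 = x$r2)

#' Construct a quadratic-with-interaction surface from known coefficients
#'
#' A surface `y = c0 + cI*I + cV*V + cI2*I^2 + cV2*V^2 + cIV*I*V` describing
#' how a thin-layer model constant varies with infrared intensity I and
#' airflow velocity V.
#'
#' @param c0,c_i,c_v,c_i2,c_v2,c_iv Surface coefficients.
#' @param response Name of the modelled constant (`"k"`, `"a"`, `"n"`, `"b"`).
#' @param r2 Optional r2 of the fit that produced the coefficients.
#' @return A `quadratic_surface` object.
#' @examples
#' ks <- quadratic_surface(0.018, 0.12, -0.051, -0.30, 0.014, 0.029, "k")
#' evaluate_quadratic_surface(ks, i = 0, v = 0) # the intercept
#' @export
quadratic_surface <- function(c0, c_i, c_v, c_i2, c_v2, c_iv,
                              response = "k", r2 = NA_real_) {
  cf <- c(c0 = c0, c_i = c_i, c_v = c_v, c_i2 = c_i2, c_v2 = c_v2,
          c_iv = c_iv)
  if (any(!is.finite(cf))) {
    abort("Surface coefficients must be finite.",
          class = "drykin_error_domain")
  }
  structure(list(coefficients = cf, response = response, r2 = r2),
            class = "quadratic_surface")
}

#' Fit a quadratic-with-interaction surface by ordinary least squares
#'
#' @param data Tibble with the response column plus `i` and `v` predictor
#'   columns.
#' @param response Name of the response column (a thin-layer model constant).
#' @return A `quadratic_surface` with fitted coefficients and r2.
#' @export
fit_quadratic_surface <- function(data, response) {
  check_columns(data, c(response, "i", "v"))
  if (nrow(data) < 6) {
    abort("Need >= 6 distinct (I, V) points.", class = "drykin_error_domain")
  }
  X <- cbind(1, data$i, data$v, data$i^2, data$v^2, data$i * data$v)
  if (qr(X)$rank < 6) {
    abort("Rank-deficient quadratic design.",
          class = "drykin_error_singular")
  }
  y <- data[[response]]
  fit <- lm(y ~ i + v + I(i^2) + I(v^2) + i:v, data = data)
  cf <- coef(fit)
  quadratic_surface(cf[[1]], cf[["i"]], cf[["v"]], cf[["I(i^2)"]],
                    cf[["I(v^2)"]], cf[["i:v"]], response = response,
                    r2 = r_squared(fit, y))
}

#' Evaluate a quadratic surface
#'
#' @param surface A `quadratic_surface`.
#' @param i,v Predictor values.
#' @return Predicted response, vectorised.
#' @export
evaluate_quadratic_surface <- function(surface, i, v) {
  stopifnot(inherits(surface, "quadratic_surface"))
  cf <- surface$coefficients
  cf[["c0"]] + cf[["c_i"]] * i + cf[["c_v"]] * v + cf[["c_i2"]] * i^2 +
    cf[["c_v2"]] * v^2 + cf[["c_iv"]] * i * v
}

#' @export
print.quadratic_surface <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<quadratic_surface> %s = %.4g + %.4g*I + %.4g*V + %.4g*I^2 + %.4g*V^2 + %.4g*I*V\n",
    x$response, cf[["c0"]], cf[["c_i"]], cf[["c_v"]], cf[["c_i2"]],
    cf[["c_v2"]], cf[["c_iv"]]))
  if (is.finite(x$r2)) cat(sprintf("  r2 = %.3f\n", x$r2))
  invisible(x)
}

#' @export
tidy.quadratic_surface <- function(x, ...) {
  tibble::tibble(response = x$response, term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.quadratic_surface <- function(x, ...) {
  tibble::tibble(response = x$response, r2 = x$r2)
}

#' Reference correlations for infrared-convective onion drying
#'
#' Published regression correlations for this dryer class, shipped for
#' worked examples and sanity checks: a linear drying-time surface
#' (time in min; IR in kW/m2, V in m/s, T in degC) and
#' quadratic-with-interaction surfaces for the four Midilli-Kucuk constants
#' (k in 1/min) against intensity and velocity.
#'
#' @return `reference_drying_time_surface()`: a [linear_surface()].
#'   `reference_midilli_surfaces()`: a named list of four
#'   [quadratic_surface()] objects (`k`, `a`, `n`, `b`).
#' @export
reference_drying_time_surface <- function() {
  linear_surface(616.12, -283.7, 50.21, -5.08)
}

#' @rdname reference_drying_time_surface
#' @export
reference_midilli_surfaces <- function() {
  list(
    k = quadratic_surface(0.018, 0.12, -0.051, -0.30, 0.014, 0.029,
                          response = "k", r2 = 0.919),
    a = quadratic_surface(2.0, -2.98, 0.42, 7.10, -0.013, 0.024,
                          response = "a", r2 = 0.911),
    n = quadratic_surface(1.74, -0.40, 0.09, 0.98, -0.057, -0.21,
                          response = "n", r2 = 0.822),
    b = quadratic_surface(0.0020, -0.04, 0.0069, 0.21, -0.007, -0.0019,
                          response = "b", r2 = 0.80)
  )
}

#' Per-condition drying time table
#'
#' Summarises a curves dataset into one drying-time row per condition, with
#' predictors in the units expected by [fit_linear_surface()] (IR in kW/m2).
#'
#' @param curves Long tibble of drying curves.
#' @return Tibble with `condition_id`, `ir` (kW/m2), `v` (m/s), `t` (degC)
#'   and `drying_time_min`.
#' @export
drying_time_table <- function(curves) {
  check_columns(curves, c("condition_id", "temperature_c", "velocity_ms",
                          "intensity_wm2", "t_s"))
  curves |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      ir = dplyr::first(.data$intensity_wm2) / 1000,
      v = dplyr::first(.data$velocity_ms),
      t = dplyr::first(.data$temperature_c),
      drying_time_min = max(.data$t_s) / 60,
      .groups = "drop"
    )
}
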