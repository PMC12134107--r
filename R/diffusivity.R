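## Slope-method diffusivity and Arrhenius activation energy -------------------

#' Estimate effective moisture diffusivity by the slope method
#'
#' Regresses `ln(MR)` on time over a falling-rate window of moisture ratios
#' (default MR in 0.05-0.8, where the one-term slab series dominates and
#' readings are not yet noise-dominated) and converts the slope to an
#' effective diffusivity via `Deff = -slope * 4 L^2 / pi^2`. The intercept is
#' freely fitted; its deviation from `ln(8/pi^2)` is reported as a
#' diagnostic.
#'
#' @param curve Tibble with `t_s` and `mr` columns (one condition).
#' @param half_thickness_m Half slab thickness L (m).
#' @param mr_window Length-2 numeric, the (lo, hi] moisture-ratio window used
#'   for the regression.
#' @return One-row tibble: `deff_m2s`, `slope_per_s`, `intercept`,
#'   `intercept_dev` (intercept minus `ln(8/pi^2)`), `r2`, `n_points`,
#'   `mr_lo`, `mr_hi`.
#' @export
estimate_deff <- function(curve, half_thickness_m, mr_window = c(0.05, 0.8)) {
  check_columns(curve, c("t_s", "mr"), arg = "curve")
  stopifnot(half_thickness_m > 0, length(mr_window) == 2,
            mr_window[1] < mr_window[2])
  sel <- is.finite(curve$mr) & curve$mr > mr_window[1] &
    curve$mr <= mr_window[2]
  if (sum(sel) < 3) {
    abort(sprintf("Only %d point(s) inside the MR window (%g, %g]; need >= 3.",
                  sum(sel), mr_window[1], mr_window[2]),
          class = "drykin_error_window")
  }
  t <- curve$t_s[sel]
  y <- log(curve$mr[sel])
  fit <- lm(y ~ t)
  slope <- coef(fit)[[2]]
  if (slope >= 0) {
    abort("Non-physical diffusivity: ln(MR) slope is non-negative.",
          class = "drykin_error_nonphysical")
  }
  tibble::tibble(
    deff_m2s = -slope * 4 * half_thickness_m^2 / pi^2,
    slope_per_s = slope,
    intercept = coef(fit)[[1]],
    intercept_dev = coef(fit)[[1]] - log(8 / pi^2),
    r2 = r_squared(fit, y),
    n_points = length(t),
    mr_lo = mr_window[1],
    mr_hi = mr_window[2]
  )
}

#' Estimate diffusivity for every condition in a dataset
#'
#' @param curves Long tibble of drying curves keyed by `condition_id`.
#' @inheritParams estimate_deff
#' @return A tibble with one [estimate_deff()] row per condition, carrying
#'   the condition columns present in `curves`.
#' @export
estimate_deff_all <- function(curves, half_thickness_m,
                              mr_window = c(0.05, 0.8)) {
  check_columns(curves, c("condition_id", "t_s", "mr"))
  cond_cols <- intersect(
    c("condition_id", "temperature_c", "velocity_ms", "intensity_wm2"),
    names(curves))
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cond_cols))) |>
    dplyr::group_modify(~ estimate_deff(.x, half_thickness_m, mr_window)) |>
    dplyr::ungroup()
}

#' Estimate activation energy by Arrhenius regression
#'
#' Fits `ln(Deff) = ln(D0) - (Ea/R) * (1/T)` by ordinary least squares over
#' the drying-air temperatures (converted to kelvin) and returns
#' `Ea = -slope * R` in kJ/mol, with `R = 8.314e-3` kJ/(mol K).
#'
#' @param deff_by_temperature Tibble with `temperature_c` and `deff_m2s`
#'   columns, at least two distinct temperatures.
#' @return One-row tibble: `ea_kj_mol`, `d0_m2s`, `r2`, `n_temperatures`.
#' @export
estimate_activation_energy <- function(deff_by_temperature) {
  check_columns(deff_by_temperature, c("temperature_c", "deff_m2s"))
  tbl <- deff_by_temperature
  if (length(unique(tbl$temperature_c)) < 2) {
    abort("Arrhenius regression needs >= 2 distinct temperatures.",
          class = "drykin_error_singular")
  }
  if (any(tbl$deff_m2s <= 0)) {
    abort("Diffusivities must be positive.", class = "drykin_error_domain")
  }
  inv_t <- 1 / celsius_to_kelvin(tbl$temperature_c)
  fit <- lm(log(tbl$deff_m2s) ~ inv_t)
  r2 <- if (nrow(tbl) > 2) r_squared(fit, log(tbl$deff_m2s)) else 1
  tibble::tibble(
    ea_kj_mol = -coef(fit)[[2]] * GAS_CONSTANT_KJ,
    d0_m2s = exp(coef(fit)[[1]]),
    r2 = r2,
    n_temperatures = length(unique(tbl$temperature_c))
  )
}

#' Activation energy per (velocity, intensity) cell
#'
#' Groups a per-condition diffusivity table by airflow velocity and infrared
#' intensity and runs the Arrhenius regression across temperatures within
#' each cell.
#'
#' @param deff_tbl Output of [estimate_deff_all()] including `temperature_c`,
#'   `velocity_ms`, `intensity_wm2`.
#' @return Tibble with one [estimate_activation_energy()] row per
#'   (velocity, intensity) pair.
#' @export
activation_energy_by_group <- function(deff_tbl) {
  check_columns(deff_tbl, c("temperature_c", "velocity_ms", "intensity_wm2",
                            "deff_m2s"))
  deff_tbl |>
    dplyr::group_by(.data$velocity_ms, .data$intensity_wm2) |>
    dplyr::group_modify(~ estimate_activation_energy(.x)) |>
    dplyr::ungroup()
}

#' Per-interval drying rate
#'
#' Finite-difference drying rate on dry basis,
#' `Dr_i = (M_{t+dt} - M_t) / dt` (1/s, negative while drying).
#'
#' @param curve Tibble with strictly increasing `t_s` and `mc_db` columns.
#' @return Tibble with `t_start_s`, `t_end_s`, `rate_per_s`
#'   (length `n_points - 1`).
#' @export
drying_rate <- function(curve) {
  check_columns(curve, c("t_s", "mc_db"), arg = "curve")
  if (nrow(curve) < 2) {
    abort("Need at least two time points.", class = "drykin_error_domain")
  }
  if (any(diff(curve$t_s) <= 0)) {
    abort("Time must be strictly increasing.",
          class = "drykin_error_ordering")
  }
  tibble::tibble(
    t_start_s = head(curve$t_s, -1),
    t_end_s = tail(curve$t_s, -1),
    rate_per_s = diff(curve$mc_db) / diff(curve$t_s)
  )
}
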