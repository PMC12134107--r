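#' Parameters of the synthetic drying-curve generator
#'
#' Bundles the physical and sampling parameters used to simulate thin-layer
#' drying curves from the Fick slab series with an Arrhenius-in-temperature
#' effective diffusivity. Defaults describe the study conditions emulated by
#' the package: 4 mm slices dried two-sided (half thickness 2 mm) from 85.8%
#' wet-basis moisture down to about 6% wb, with a reference diffusivity of
#' 5e-10 m2/s at 50 degC / 3500 W/m2 / 0.7 m/s, activation energy 25 kJ/mol,
#' diffusivity increasing with infrared intensity and decreasing with airflow,
#' and mass readings sampled every 300 s.
#'
#' The effective diffusivity for a condition (T, V, IR) is
#' `d_ref * exp(-Ea/R * (1/T - 1/T_ref)) * (IR/IR_ref)^ir_exponent *
#' (V/V_ref)^velocity_exponent` with temperatures in kelvin.
#'
#' @param half_thickness_m Half slab thickness L (m).
#' @param mc0_wb Initial wet-basis moisture fraction in (0, 1).
#' @param mc_final_wb Termination wet-basis moisture fraction, below `mc0_wb`.
#' @param d_ref_m2s Reference effective diffusivity (m2/s) at the reference
#'   condition.
#' @param ea_kj_mol Generative activation energy (kJ/mol).
#' @param t_ref_c,ir_ref_wm2,v_ref_ms Reference temperature (degC), infrared
#'   intensity (W/m2) and velocity (m/s) at which `d_ref_m2s` applies.
#' @param ir_exponent,velocity_exponent Dimensionless power-law modifiers of
#'   diffusivity in IR and V.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on mass readings (0 for noise-free curves).
#' @param dt_s Sampling interval (s).
#' @param n_series_terms Number of odd terms retained in the Fick slab series.
#' @param max_time_s Longest admissible drying time (s); a curve that has not
#'   reached `mc_final_wb` by then signals infeasible parameters.
#' @param initial_mass_g Initial batch mass on the tray (g).
#' @param seed Integer seed; every stochastic draw in the generator is
#'   deterministic given the seed.
#'
#' @return A `generator_params` list.
#' @export
generator_params <- function(half_thickness_m = 0.002,
                             mc0_wb = 0.858,
                             mc_final_wb = 0.06,
                             d_ref_m2s = 5e-10,
                             ea_kj_mol = 25,
                             t_ref_c = 50,
                             ir_ref_wm2 = 3500,
                             v_ref_ms = 0.7,
                             ir_exponent = 0.25,
                             velocity_exponent = -0.15,
                             noise_cv = 0,
                             dt_s = 300,
                             n_series_terms = 500,
                             max_time_s = 48 * 3600,
                             initial_mass_g = 500,
                             seed = 1L) {
  gp <- list(
    half_thickness_m = half_thickness_m, mc0_wb = mc0_wb,
    mc_final_wb = mc_final_wb, d_ref_m2s = d_ref_m2s,
    ea_kj_mol = ea_kj_mol, t_ref_c = t_ref_c, ir_ref_wm2 = ir_ref_wm2,
    v_ref_ms = v_ref_ms, ir_exponent = ir_exponent,
    velocity_exponent = velocity_exponent, noise_cv = noise_cv,
    dt_s = dt_s, n_series_terms = as.integer(n_series_terms),
    max_time_s = max_time_s, initial_mass_g = initial_mass_g,
    seed = as.integer(seed)
  )
  validate_generator_params(gp)
  structure(gp, class = "generator_params")
}

validate_generator_params <- function(gp) {
  ok <- gp$half_thickness_m > 0 && gp$d_ref_m2s > 0 &&
    gp$mc_final_wb > 0 && gp$mc_final_wb < gp$mc0_wb && gp$mc0_wb < 1 &&
    gp$noise_cv >= 0 && gp$n_series_terms >= 1 && gp$dt_s > 0 &&
    gp$initial_mass_g > 0 && gp$max_time_s > 0
  if (!ok) {
    abort("Invalid generator parameters: check thickness, moisture bounds, diffusivity, noise and sampling settings.",
          class = "drykin_error_domain")
  }
  invisible(gp)
}

#' Generative effective diffusivity for each condition
#'
#' Evaluates the generator's Arrhenius-with-power-law diffusivity model at
#' each row of a conditions table.
#'
#' @param conditions Conditions tibble (see [make_conditions_grid()]).
#' @param gp A [generator_params()] object.
#' @return The conditions tibble with a `deff_m2s` column appended.
#' @export
deff_from_conditions <- function(conditions, gp = generator_params()) {
  check_columns(conditions, c("temperature_c", "velocity_ms", "intensity_wm2"))
  tk <- celsius_to_kelvin(conditions$temperature_c)
  tref <- celsius_to_kelvin(gp$t_ref_c)
  deff <- gp$d_ref_m2s *
    exp(-gp$ea_kj_mol / GAS_CONSTANT_KJ * (1 / tk - 1 / tref)) *
    (conditions$intensity_wm2 / gp$ir_ref_wm2)^gp$ir_exponent *
    (conditions$velocity_ms / gp$v_ref_ms)^gp$velocity_exponent
  dplyr::mutate(conditions, deff_m2s = deff)
}

#' Simulate one thin-layer drying curve
#'
#' Generates a seeded drying curve for a single condition from the Fick slab
#' series. The noise-free mean trajectory is exactly
#' `fick_series_mr(t, deff, L, n_terms)`; multiplicative lognormal noise with
#' coefficient of variation `noise_cv` (a balance-error model, unit mean) is
#' applied to the mass readings, and dry-basis moisture and moisture ratio are
#' recomputed from the noisy masses. The curve is truncated at the first
#' sample whose mean wet-basis moisture content falls to `mc_final_wb`.
#'
#' @param condition A one-row conditions tibble (or a list with
#'   `condition_id`, `temperature_c`, `velocity_ms`, `intensity_wm2`).
#' @param gp A [generator_params()] object.
#' @param deff_m2s Optional explicit effective diffusivity (m2/s); when `NULL`
#'   it is derived from the condition via [deff_from_conditions()].
#' @param seed Seed for the noise draws; defaults to `gp$seed`.
#'
#' @return A tibble with columns `condition_id`, `temperature_c`,
#'   `velocity_ms`, `intensity_wm2`, `t_s`, `mass_g`, `mc_db`, `mc_wb`, `mr`.
#' @export
simulate_drying_curve <- function(condition, gp = generator_params(),
                                  deff_m2s = NULL, seed = gp$seed) {
  validate_generator_params(gp)
  condition <- tibble::as_tibble(condition)
  if (nrow(condition) != 1) {
    abort("`condition` must describe exactly one drying condition.",
          class = "drykin_error_domain")
  }
  if (is.null(deff_m2s)) {
    deff_m2s <- deff_from_conditions(condition, gp)$deff_m2s
  }
  stopifnot(deff_m2s > 0)

  t_s <- seq(0, gp$max_time_s, by = gp$dt_s)
  mr_mean <- fick_series_mr(t_s, deff_m2s, gp$half_thickness_m,
                            n_terms = gp$n_series_terms)
  mc_db0 <- wb_to_db(gp$mc0_wb)
  mc_db_mean <- mr_mean * mc_db0
  mc_wb_mean <- db_to_wb(mc_db_mean)

  stop_at <- which(mc_wb_mean <= gp$mc_final_wb)[1]
  if (is.na(stop_at)) {
    abort(sprintf("Curve did not reach %.1f%% wb within max_time_s = %g s; generator parameters are infeasible.",
                  100 * gp$mc_final_wb, gp$max_time_s),
          class = "drykin_error_infeasible")
  }
  keep <- seq_len(stop_at)
  t_s <- t_s[keep]
  mc_db_mean <- mc_db_mean[keep]

  w_dry <- gp$initial_mass_g * (1 - gp$mc0_wb)
  mass_mean <- w_dry * (1 + mc_db_mean)
  if (gp$noise_cv > 0) {
    sdlog <- sqrt(log(1 + gp$noise_cv^2))
    mass_g <- withr::with_seed(
      seed,
      mass_mean * exp(rnorm(length(mass_mean), -sdlog^2 / 2, sdlog))
    )
  } else {
    mass_g <- mass_mean
  }
  mc_db <- mass_g / w_dry - 1
  tibble::tibble(
    condition_id = condition$condition_id %||% "cond",
    temperature_c = condition$temperature_c,
    velocity_ms = condition$velocity_ms,
    intensity_wm2 = condition$intensity_wm2,
    t_s = t_s,
    mass_g = mass_g,
    mc_db = mc_db,
    mc_wb = db_to_wb(mc_db),
    mr = mc_db / mc_db0
  )
}

#' Simulate a full drying experiment
#'
#' Runs [simulate_drying_curve()] over every row of a conditions table. Each
#' condition uses the deterministic seed `gp$seed + row index`, so the whole
#' dataset is reproducible for a fixed `gp`.
#'
#' @param conditions Conditions tibble (see [make_conditions_grid()]).
#' @param gp A [generator_params()] object.
#' @return A long tibble of curves, one block of rows per condition.
#' @export
simulate_experiment <- function(conditions = make_conditions_grid(),
                                gp = generator_params()) {
  conditions <- deff_from_conditions(conditions, gp)
  purrr::map_dfr(seq_len(nrow(conditions)), function(i) {
    simulate_drying_curve(conditions[i, ], gp,
                          deff_m2s = conditions$deff_m2s[i],
                          seed = gp$seed + i)
  })
}

#' Response-surface specification for synthetic quality tables
#'
#' Defines, for each quality metric, a linear response surface in the coded
#' process variables (each factor mapped onto `[-1, 1]` over its grid range)
#' plus a Gaussian noise standard deviation. Defaults emulate the monotone
#' trends the analysis expects: water activity between 0.40 and 0.49 and
#' decreasing with infrared intensity; total colour change and browning
#' increasing with intensity and decreasing with airflow; shrinkage ratio
#' decreasing with intensity; vitamin C retention decreasing with temperature
#' and intensity.
#'
#' Colour is generated by displacing a fresh-sample CIELAB reference along a
#' fixed browning direction (lower L*, higher a*/b*) by the surface value of
#' the total colour change, so the browning index inherits the colour-change
#' trend.
#'
#' @param surfaces Named list of blocks, each
#'   `list(intercept, t, v, ir, sd)` giving the coded-variable coefficients
#'   and noise SD for `aw`, `delta_e`, `sr`, `rr` and `vc_retention`.
#' @param lab_reference Fresh-sample CIELAB reference `c(l0, a0, b0)`.
#' @param browning_direction Unit vector in Lab space along which colour
#'   change accumulates.
#' @param vol_fresh_cm3 Fresh sample volume (cm3).
#' @param w_dry_g Dried sample weight used for rehydration (g).
#' @param vc_0_mg_g Fresh vitamin C concentration (mg/g).
#'
#' @return A `quality_surface_spec` list.
#' @export
quality_surface_spec <- function(
    surfaces = list(
      aw = list(intercept = 0.445, t = -0.012, v = -0.005, ir = -0.015,
                sd = 0.004),
      delta_e = list(intercept = 11.0, t = 1.8, v = -2.2, ir = 3.0, sd = 0.3),
      sr = list(intercept = 0.18, t = -0.02, v = 0.015, ir = -0.03,
                sd = 0.005),
      rr = list(intercept = 4.75, t = 0.08, v = -0.06, ir = 0.12, sd = 0.05),
      vc_retention = list(intercept = 0.81, t = -0.06, v = -0.02, ir = -0.08,
                          sd = 0.01)
    ),
    lab_reference = c(l0 = 80, a0 = 0, b0 = 15),
    browning_direction = c(-0.8, 0.5, sqrt(1 - 0.8^2 - 0.5^2)),
    vol_fresh_cm3 = 20,
    w_dry_g = 10,
    vc_0_mg_g = 24) {
  needed <- c("aw", "delta_e", "sr", "rr", "vc_retention")
  if (!all(needed %in% names(surfaces))) {
    abort(sprintf("`surfaces` must contain blocks: %s.",
                  paste(needed, collapse = ", ")),
          class = "drykin_error_schema")
  }
  structure(
    list(surfaces = surfaces, lab_reference = lab_reference,
         browning_direction = browning_direction / sqrt(sum(browning_direction^2)),
         vol_fresh_cm3 = vol_fresh_cm3, w_dry_g = w_dry_g,
         vc_0_mg_g = vc_0_mg_g),
    class = "quality_surface_spec"
  )
}

eval_quality_surface <- function(block, t_coded, v_coded, ir_coded) {
  block$intercept + block$t * t_coded + block$v * v_coded +
    block$ir * ir_coded
}

#' Simulate a per-condition quality table
#'
#' Evaluates the configured quality response surfaces at every condition,
#' adds seeded Gaussian noise, and materialises the raw measurement columns
#' the quality module consumes (CIELAB coordinates with fresh reference,
#' fresh/dried volumes, dried/rehydrated weights, vitamin C titres).
#'
#' @param conditions Conditions tibble.
#' @param spec A [quality_surface_spec()].
#' @param seed Integer seed for the noise draws.
#' @param n_reps Number of replicate records per condition.
#'
#' @return A tibble with one row per condition and replicate: condition
#'   columns plus `rep`, `aw`, `l`, `a`, `b`, `l0`, `a0`, `b0`, `vol_fresh`,
#'   `vol_dry`, `w_dry`, `w_rehydrated`, `vc_t`, `vc_0`.
#' @export
simulate_quality_table <- function(conditions = make_conditions_grid(),
                                   spec = quality_surface_spec(),
                                   seed = 1L, n_reps = 1L) {
  coded <- code_conditions(conditions)
  coded <- tidyr::expand_grid(
    dplyr::mutate(coded, .row = dplyr::row_number()),
    rep = seq_len(n_reps)
  )
  n <- nrow(coded)
  draw <- function(block) {
    eval_quality_surface(block, coded$t_coded, coded$v_coded,
                         coded$ir_coded) +
      if (block$sd > 0) rnorm(n, 0, block$sd) else 0
  }
  withr::with_seed(seed, {
    aw <- draw(spec$surfaces$aw)
    de <- pmax(draw(spec$surfaces$delta_e), 0)
    sr <- draw(spec$surfaces$sr)
    rr <- draw(spec$surfaces$rr)
    vc <- draw(spec$surfaces$vc_retention)
  })
  dir <- spec$browning_direction
  ref <- spec$lab_reference
  tibble::tibble(
    condition_id = coded$condition_id,
    temperature_c = coded$temperature_c,
    velocity_ms = coded$velocity_ms,
    intensity_wm2 = coded$intensity_wm2,
    rep = coded$rep,
    aw = aw,
    l = ref[["l0"]] + dir[1] * de,
    a = ref[["a0"]] + dir[2] * de,
    b = ref[["b0"]] + dir[3] * de,
    l0 = ref[["l0"]], a0 = ref[["a0"]], b0 = ref[["b0"]],
    vol_fresh = spec$vol_fresh_cm3,
    vol_dry = spec$vol_fresh_cm3 * (1 - sr),
    w_dry = spec$w_dry_g,
    w_rehydrated = rr * spec$w_dry_g,
    vc_t = vc * spec$vc_0_mg_g,
    vc_0 = spec$vc_0_mg_g
  )
}
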