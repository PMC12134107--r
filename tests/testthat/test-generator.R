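test_that("noise-free curves start at 85.8% wb, end at or below 6.3% wb, and decay monotonically", {
  gp <- generator_params()
  curve <- simulate_drying_curve(ref_condition(), gp)
  expect_equal(curve$mc_wb[1], 0.858, tolerance = 1e-3)
  expect_lte(tail(curve$mc_wb, 1), 0.063)
  expect_true(all(diff(curve$mr) <= 0))
  expect_true(all(curve$mr > 0 & curve$mr <= 1))
})

test_that("the noise-free generator is exactly the Fick series oracle", {
  gp <- generator_params()
  cond <- deff_from_conditions(ref_condition(), gp)
  curve <- simulate_drying_curve(cond, gp, deff_m2s = cond$deff_m2s)
  oracle <- fick_series_mr(curve$t_s, cond$deff_m2s, gp$half_thickness_m,
                           n_terms = gp$n_series_terms)
  expect_equal(curve$mr, oracle, tolerance = 1e-12)
})

test_that("dry mass is conserved along simulated curves and Wt >= Wd", {
  gp <- generator_params(noise_cv = 0.01)
  curve <- simulate_drying_curve(ref_condition(), gp, seed = 7)
  w_dry <- gp$initial_mass_g * (1 - gp$mc0_wb)
  expect_equal(curve$mass_g / w_dry - 1, curve$mc_db, tolerance = 1e-12)
  expect_true(all(curve$mass_g >= w_dry))
})

test_that("seeded generation is bit-reproducible and infeasible settings error", {
  gp <- generator_params(noise_cv = 0.02, seed = 42)
  a <- simulate_experiment(make_conditions_grid(c(40, 60), 0.3, 1500), gp)
  b <- simulate_experiment(make_conditions_grid(c(40, 60), 0.3, 1500), gp)
  expect_identical(a, b)
  expect_error(
    simulate_drying_curve(ref_condition(),
                          generator_params(max_time_s = 600)),
    class = "drykin_error_infeasible")
  expect_error(generator_params(mc_final_wb = 0.9),
               class = "drykin_error_domain")
})

test_that("generative diffusivity follows the configured trends and magnitude", {
  tbl <- deff_from_conditions(make_conditions_grid(), generator_params())
  expect_true(all(tbl$deff_m2s > 1e-10 & tbl$deff_m2s < 1e-9))
  by_ir <- tbl |>
    dplyr::arrange(temperature_c, velocity_ms, intensity_wm2) |>
    dplyr::group_by(temperature_c, velocity_ms) |>
    dplyr::summarise(inc = all(diff(deff_m2s) > 0), .groups = "drop")
  expect_true(all(by_ir$inc))
  by_v <- tbl |>
    dplyr::arrange(temperature_c, intensity_wm2, velocity_ms) |>
    dplyr::group_by(temperature_c, intensity_wm2) |>
    dplyr::summarise(dec = all(diff(deff_m2s) < 0), .groups = "drop")
  expect_true(all(by_v$dec))
})

test_that("noiseless quality surfaces respect the study ranges and corner ordering", {
  q <- noiseless_quality()
  expect_true(all(q$aw >= 0.40 & q$aw <= 0.49))
  aw_cool <- q$aw[q$condition_id == "T40_V0.3_IR1500"]
  aw_hot <- q$aw[q$condition_id == "T60_V0.3_IR5500"]
  expect_gt(aw_cool, aw_hot)
  sr <- shrinkage_ratio(q$vol_dry, q$vol_fresh)
  expect_true(all(sr > 0 & sr < 1))
  expect_true(all(q$w_rehydrated / q$w_dry > 1))
  expect_true(all(q$aw > 0 & q$aw < 0.6))
})

test_that("quality tables are seed-reproducible and replicate correctly", {
  a <- simulate_quality_table(make_conditions_grid(), seed = 5)
  b <- simulate_quality_table(make_conditions_grid(), seed = 5)
  expect_identical(a, b)
  r <- simulate_quality_table(make_conditions_grid(), seed = 5, n_reps = 4)
  expect_equal(nrow(r), 27 * 4)
  expect_equal(sort(unique(r$rep)), 1:4)
})
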