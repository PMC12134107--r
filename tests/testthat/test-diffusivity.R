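test_that("the slope method inverts an exact one-term exponential in closed form", {
  s <- 1e-4
  L <- 0.002
  curve <- one_term_curve(s)
  res <- estimate_deff(curve, L)
  expect_equal(res$deff_m2s, 4 * L^2 * s / pi^2, tolerance = 1e-10)
  expect_equal(res$intercept_dev, 0, tolerance = 1e-10)
  expect_equal(res$r2, 1, tolerance = 1e-12)
})

test_that("one-term generated curves recover the generating diffusivity", {
  gp <- generator_params(n_series_terms = 1)
  for (deff in c(2.6e-10, 5.05e-10, 8.9e-10)) {
    curve <- simulate_drying_curve(ref_condition(), gp, deff_m2s = deff)
    est <- estimate_deff(curve, gp$half_thickness_m)$deff_m2s
    expect_lt(abs(est / deff - 1), 0.005)
  }
})

test_that("noisy slope estimates stay within 10% median relative error", {
  gp <- generator_params(noise_cv = 0.01)
  deff <- 5.05e-10
  errs <- vapply(1:100, function(s) {
    curve <- simulate_drying_curve(ref_condition(), gp, deff_m2s = deff,
                                   seed = s)
    abs(estimate_deff(curve, gp$half_thickness_m)$deff_m2s / deff - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("non-physical slopes and starved windows are rejected", {
  rising <- tibble::tibble(t_s = seq(0, 3000, 300),
                           mr = seq(0.1, 0.7, length.out = 11))
  expect_error(estimate_deff(rising, 0.002),
               class = "drykin_error_nonphysical")
  short <- tibble::tibble(t_s = c(0, 300), mr = c(0.5, 0.4))
  expect_error(estimate_deff(short, 0.002), class = "drykin_error_window")
})

test_that("the estimate only uses the MR window and ignores mass scale", {
  curve <- one_term_curve(1e-4)
  res <- estimate_deff(curve, 0.002)
  expect_true(all(curve$mr[curve$mr > 0.05 & curve$mr <= 0.8] |>
                    length() == res$n_points))
  # MR is scale-free: adding a mass column or rescaling it cannot matter
  curve$mass_g <- 500 * curve$mr + 71
  expect_equal(estimate_deff(curve, 0.002)$deff_m2s, res$deff_m2s)
})

test_that("Arrhenius regression recovers exact parameters and degenerates sensibly", {
  temps <- c(40, 50, 60)
  ea <- 25
  d0 <- 1e-6
  deff <- d0 * exp(-ea / 8.314e-3 / (temps + 273.15))
  res <- estimate_activation_energy(
    tibble::tibble(temperature_c = temps, deff_m2s = deff))
  expect_lt(abs(res$ea_kj_mol / ea - 1), 1e-6)
  expect_equal(res$d0_m2s, d0, tolerance = 1e-6)

  flat <- estimate_activation_energy(
    tibble::tibble(temperature_c = temps, deff_m2s = rep(3e-10, 3)))
  expect_equal(flat$ea_kj_mol, 0, tolerance = 1e-12)

  expect_error(estimate_activation_energy(
    tibble::tibble(temperature_c = c(50, 50), deff_m2s = c(1e-10, 2e-10))),
    class = "drykin_error_singular")
})

test_that("simulate -> slope -> Arrhenius round-trips the generative activation energy", {
  draws <- withr::with_seed(21, tibble::tibble(
    d_ref = runif(20, 2e-10, 8e-10),
    ea = runif(20, 18, 28.95)))
  for (i in seq_len(nrow(draws))) {
    gp <- generator_params(d_ref_m2s = draws$d_ref[i],
                           ea_kj_mol = draws$ea[i])
    curves <- simulate_experiment(
      make_conditions_grid(c(40, 50, 60), 0.7, 3500), gp)
    deff_tbl <- estimate_deff_all(curves, gp$half_thickness_m)
    res <- estimate_activation_energy(deff_tbl)
    expect_lt(abs(res$ea_kj_mol / draws$ea[i] - 1), 0.02)
  }
})

test_that("drying rate is the finite-difference dry-basis derivative", {
  lin <- tibble::tibble(t_s = seq(0, 5000, 1000),
                        mc_db = seq(6, 1, length.out = 6))
  dr <- drying_rate(lin)
  expect_equal(nrow(dr), 5)
  expect_equal(dr$rate_per_s, rep(-1e-3, 5))
  flat <- tibble::tibble(t_s = seq(0, 5000, 1000), mc_db = rep(2, 6))
  expect_equal(drying_rate(flat)$rate_per_s, rep(0, 5))
  expect_error(drying_rate(tibble::tibble(t_s = c(0, 300, 300),
                                          mc_db = c(3, 2, 1))),
               class = "drykin_error_ordering")
  # falling-rate period: |Dr| non-increasing after the first interval
  gp <- generator_params()
  curve <- simulate_drying_curve(ref_condition(), gp)
  rates <- drying_rate(curve)$rate_per_s
  expect_true(all(diff(abs(rates[-1])) <= 1e-12))
})
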