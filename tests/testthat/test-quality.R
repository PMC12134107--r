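test_that("moisture conversions match hand arithmetic and round-trip", {
  expect_equal(moisture_db(100, 40), 1.5)
  expect_equal(moisture_db(40, 40), 0)
  expect_error(moisture_db(100, 0), class = "drykin_error_domain")
  expect_equal(wb_to_db(0.858), 0.858 / 0.142)
  wb <- seq(0.05, 0.95, by = 0.05)
  expect_equal(db_to_wb(wb_to_db(wb)), wb, tolerance = 1e-12)
  expect_error(wb_to_db(1), class = "drykin_error_domain")
})

test_that("delta E is a symmetric metric with the hand value 5.0", {
  expect_equal(delta_e(53, 4, 10, 50, 0, 10), 5)
  expect_equal(delta_e(50, 0, 10, 50, 0, 10), 0)
  expect_equal(delta_e(50, 0, 10, 53, 4, 10), 5) # symmetry
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- runif(3, 0, 100)
      q <- runif(3, 0, 100)
      r <- runif(3, 0, 100)
      d_pq <- delta_e(p[1], p[2], p[3], q[1], q[2], q[3])
      d_qr <- delta_e(q[1], q[2], q[3], r[1], r[2], r[3])
      d_pr <- delta_e(p[1], p[2], p[3], r[1], r[2], r[3])
      expect_lte(d_pr, d_pq + d_qr + 1e-12)
    }
  })
})

test_that("browning index matches its chromaticity definition", {
  expect_equal(browning_index(50, 10, 20), 21.02, tolerance = 1e-3)
  # a* chosen so that X = 0.31 exactly -> BI = 0
  l <- 50; b <- 20
  a0 <- (0.31 * (6.645 * l - 3.012 * b) - 1.75 * l) / (1 - 0.31)
  expect_equal(browning_index(l, a0, b), 0, tolerance = 1e-9)
  # increasing a* at fixed L*, b* increases BI (positive denominator)
  bi <- browning_index(50, c(5, 10, 15), 20)
  expect_true(all(diff(bi) > 0))
  expect_error(browning_index(0, 0, 0), class = "drykin_error_domain")
})

test_that("shrinkage, rehydration and vitamin C ratios match their definitions", {
  expect_equal(shrinkage_ratio(20, 20), 0)
  expect_equal(shrinkage_ratio(15, 20), 0.25)
  expect_equal(shrinkage_ratio(16.8, 20), 0.16)
  expect_warning(shrinkage_ratio(25, 20), "swelling")
  expect_equal(rehydration_ratio(10, 10), 1)
  expect_equal(rehydration_ratio(35, 10), 3.5)
  expect_equal(rehydration_ratio(51, 10), 5.1)
  expect_equal(vitamin_c_retention(24, 24), 1)
  expect_equal(vitamin_c_retention(12, 24), 0.5)
  expect_equal(vitamin_c_retention(0, 24), 0)
  expect_warning(vitamin_c_retention(30, 24), "exceed")
})

test_that("water-activity screening flags the closed 0.6 boundary", {
  rec <- tibble::tibble(aw = c(0.45, 0.59, 0.60, 0.75))
  out <- screen_water_activity(rec)
  expect_equal(out$stable, c(TRUE, TRUE, FALSE, FALSE))
  empty <- screen_water_activity(tibble::tibble(aw = numeric()))
  expect_equal(nrow(empty), 0)
  expect_true("stable" %in% names(empty))
})

test_that("computed indices on the noiseless table reproduce the configured IR trends", {
  metrics <- compute_quality_metrics(noiseless_quality())
  expect_true(all(metrics$stable))
  trends <- metrics |>
    dplyr::arrange(temperature_c, velocity_ms, intensity_wm2) |>
    dplyr::group_by(temperature_c, velocity_ms) |>
    dplyr::summarise(
      de_up = all(diff(delta_e) > 0),
      bi_up = all(diff(browning_index) > 0),
      aw_down = all(diff(aw) < 0),
      sr_down = all(diff(shrinkage_ratio) < 0),
      vc_down = all(diff(vitamin_c_retention) < 0),
      .groups = "drop")
  expect_true(all(unlist(trends[, -(1:2)])))
})
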