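test_that("the registry holds the eleven models with their parameter counts", {
  reg <- thin_layer_models()
  expect_equal(nrow(reg), 11)
  counts <- c(newton = 1, page = 2, modified_page = 2, henderson_pabis = 2,
              logarithmic = 3, midilli_kucuk = 4, wang_singh = 2, verma = 3,
              two_term = 4, modified_henderson_pabis = 6, thomson = 2)
  expect_equal(setNames(reg$n_params, reg$name)[names(counts)], counts)
  expect_equal(get_model("Newton")$params[[1]], "k")
  expect_error(get_model("nope"), class = "drykin_error_lookup")
})

test_that("forward models return MR = 1 at t = 0 with canonical parameters", {
  cases <- list(
    newton = c(k = 0.01),
    page = c(k = 0.01, n = 1.2),
    modified_page = c(k = 0.01, n = 1.2),
    henderson_pabis = c(a = 1, k = 0.01),
    logarithmic = c(a = 1, k = 0.01, c = 0),
    midilli_kucuk = c(a = 1, k = 0.01, n = 1.2, b = 0),
    wang_singh = c(a = -0.01, b = 2e-5),
    verma = c(a = 0.6, k = 0.01, g = 0.002),
    two_term = c(a = 0.6, k0 = 0.01, b = 0.4, k1 = 0.002),
    modified_henderson_pabis = c(a = 0.5, k = 0.01, b = 0.3, g = 0.005,
                                 c = 0.2, h = 0.001),
    thomson = c(a = -100, b = -5)
  )
  for (m in names(cases)) {
    expect_equal(evaluate_model(m, cases[[m]], 0), 1,
                 info = m, tolerance = 1e-12)
  }
})

test_that("nested models reduce to Newton algebraically", {
  t <- c(0, 50, 100, 400)
  newton <- evaluate_model("newton", c(k = 0.01), t)
  expect_equal(evaluate_model("page", c(k = 0.01, n = 1), t), newton)
  expect_equal(
    evaluate_model("midilli_kucuk", c(a = 1, k = 0.01, n = 1, b = 0), t),
    newton)
  expect_equal(evaluate_model("modified_page", c(k = 0.01, n = 1), t),
               newton)
})

test_that("incomplete or non-finite parameters are rejected", {
  expect_error(evaluate_model("page", c(k = 0.01), 1),
               class = "drykin_error_parameter")
  expect_error(evaluate_model("newton", c(k = NaN), 1),
               class = "drykin_error_parameter")
  expect_error(evaluate_model("newton", c(k = 0.01), -1),
               class = "drykin_error_domain")
})

test_that("the Fick series starts at its truncated sum and decays below 1e-5 at large Fourier number", {
  expect_equal(fick_series_mr(0, 5e-10, 0.002, n_terms = 1), 8 / pi^2)
  rate <- pi^2 * 5e-10 / (4 * 0.002^2)
  t_big <- 5.5 * 4 * 0.002^2 / 5e-10 # Fourier number > 5
  expect_lt(fick_series_mr(t_big, 5e-10, 0.002, 200), 1e-5)
  t_grid <- seq(0, 3e4, length.out = 50)
  mr <- fick_series_mr(t_grid, 5e-10, 0.002, 200)
  expect_true(all(diff(mr) <= 0))
  expect_true(all(mr > 0 & mr <= 1))
})

test_that("one-term and many-term series agree once the one-term regime is reached", {
  deff <- 5e-10
  L <- 0.002
  rate <- pi^2 * deff / (4 * L^2)
  t_grid <- seq(0, 1e5, length.out = 400)
  valid <- rate * t_grid > 2
  diff_series <- abs(fick_series_mr(t_grid, deff, L, 1) -
                       fick_series_mr(t_grid, deff, L, 200))
  expect_true(all(diff_series[valid] < 1e-6))
})

test_that("Thomson inversion matches its closed forms and round-trips", {
  expect_equal(thomson_predict_mr(c(a = -100, b = -5), 0), 1)
  expect_equal(thomson_predict_mr(c(a = -100, b = 0), 50), exp(-0.5))
  withr::with_seed(99, {
    for (i in 1:20) {
      a <- -runif(1, 50, 500)
      b <- runif(1, -20, 20)
      mr_star <- runif(1, 0.05, 0.95)
      y <- log(mr_star)
      t_star <- a * y + b * y^2
      if (t_star < 0) next # outside the drying branch for this draw
      expect_equal(thomson_predict_mr(c(a = a, b = b), t_star), mr_star,
                   tolerance = 1e-10)
    }
  })
  expect_error(thomson_predict_mr(c(a = 100, b = 0), 50),
               class = "drykin_error_domain")
})
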