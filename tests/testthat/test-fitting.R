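test_that("goodness reproduces its identities and hand example", {
  perfect <- goodness(c(1, 0.7, 0.4), c(1, 0.7, 0.4), 1)
  expect_equal(unlist(perfect[, c("r2", "chi2", "rmse")], use.names = FALSE),
               c(1, 0, 0))
  hand <- goodness(c(1.0, 0.5), c(0.9, 0.6), n_params = 1)
  expect_equal(hand$rmse, 0.1)
  expect_equal(hand$chi2, 0.02)
  # doubling every residual quadruples chi2
  obs <- c(1, 0.8, 0.5, 0.2)
  pred <- obs + c(0.01, -0.02, 0.015, -0.01)
  pred2 <- obs + 2 * (pred - obs)
  expect_equal(goodness(obs, pred2, 1)$chi2, 4 * goodness(obs, pred, 1)$chi2)
  expect_error(goodness(c(1, 1, 1), c(1, 0.9, 1.1), 1),
               class = "drykin_error_degenerate")
  expect_error(goodness(1:3 / 3, 1:2 / 2, 1), class = "drykin_error_domain")
})

test_that("noise-free self-fits recover parameters to machine precision", {
  t_s <- seq(0, 1200, by = 20)
  newton_curve <- tibble::tibble(t_s = t_s, mr = exp(-0.005 * t_s))
  fn <- fit_model(newton_curve, "newton")
  expect_lt(abs(fn$parameters[["k"]] / 0.005 - 1), 1e-6)
  expect_lt(fn$stats$rmse, 1e-10)

  mk <- midilli_example_curve()
  fm <- fit_model(mk$curve, "midilli_kucuk", seed = 2)
  expect_true(all(abs(fm$parameters[names(mk$params)] / mk$params - 1)
                  < 1e-3))
  expect_gt(fm$stats$r2, 0.999)
})

test_that("Thomson collapses to the Newton limit on exponential data", {
  t_s <- seq(0, 1200, by = 20)
  curve <- tibble::tibble(t_s = t_s, mr = exp(-0.004 * t_s))
  ft <- fit_model(curve, "thomson")
  expect_lt(ft$rmse_t, 1e-6)
  expect_lt(abs(ft$parameters[["b"]]), 1e-8)
  expect_equal(ft$parameters[["a"]], -250, tolerance = 1e-8)
})

test_that("log-linear closed forms agree with the nonlinear fits (oracle equivalence)", {
  t_s <- seq(0, 1500, by = 25)
  for (case in list(list(model = "newton", a = 1, k = 0.003),
                    list(model = "henderson_pabis", a = 0.95, k = 0.003))) {
    mr <- case$a * exp(-case$k * t_s)
    curve <- tibble::tibble(t_s = t_s, mr = mr)
    # independent oracle: ordinary least squares on ln(MR)
    cf <- coef(lm(log(mr) ~ t_s))
    fit <- fit_model(curve, case$model)
    expect_equal(fit$parameters[["k"]], -cf[[2]], tolerance = 1e-8,
                 info = case$model)
    if (case$model == "henderson_pabis") {
      expect_equal(fit$parameters[["a"]], exp(cf[[1]]), tolerance = 1e-8)
    }
  }
})

test_that("adding a nested parameter never increases the minimised SSR", {
  t_s <- seq(0, 1200, by = 20)
  mr <- exp(-0.005 * t_s) *
    exp(withr::with_seed(3, rnorm(length(t_s), 0, 0.01)))
  curve <- tibble::tibble(t_s = t_s, mr = mr)
  ssr <- vapply(c("newton", "page", "midilli_kucuk"),
                function(m) sum(fit_model(curve, m, seed = 1)$residuals^2),
                numeric(1))
  expect_lte(ssr[["page"]], ssr[["newton"]] + 1e-12)
  expect_lte(ssr[["midilli_kucuk"]], ssr[["page"]] + 1e-12)
})

test_that("fits are invariant to the time unit after rescaling rate constants", {
  t_s <- seq(0, 1200, by = 20)
  mr <- exp(-0.004 * t_s) *
    exp(withr::with_seed(11, rnorm(length(t_s), 0, 0.01)))
  sec <- fit_model(tibble::tibble(t_s = t_s, mr = mr), "page", seed = 1)
  minute <- fit_model(tibble::tibble(t_s = t_s / 60, mr = mr), "page",
                      seed = 1)
  expect_equal(minute$stats$rmse, sec$stats$rmse, tolerance = 1e-6)
  expect_equal(minute$parameters[["n"]], sec$parameters[["n"]],
               tolerance = 1e-4)
  # Page's k carries units 1/time^n
  expect_equal(minute$parameters[["k"]],
               sec$parameters[["k"]] * 60^sec$parameters[["n"]],
               tolerance = 1e-4)
})

test_that("degenerate and undersized curves are rejected", {
  expect_error(fit_model(tibble::tibble(t_s = 1:10, mr = rep(0.5, 10)),
                         "newton"),
               class = "drykin_error_degenerate")
  expect_error(
    fit_model(tibble::tibble(t_s = 1:4, mr = exp(-0.1 * (1:4))),
              "modified_henderson_pabis"),
    class = "drykin_error_domain")
})

test_that("the three-metric ranking prefers parsimony on ties and ranks the true model first", {
  tied <- tibble::tibble(
    model = c("big", "small"), r2 = c(0.99, 0.99), chi2 = c(1e-4, 1e-4),
    rmse = c(0.01, 0.01), n_params = c(4L, 1L), converged = TRUE)
  ranked <- select_best(tied)
  expect_equal(ranked$model[1], "small")
  single <- select_best(tied[1, ])
  expect_equal(nrow(single), 1)
  expect_equal(single$rank, 1L)
  expect_error(select_best(dplyr::mutate(tied, converged = FALSE)),
               class = "drykin_error_selection")

  mk <- midilli_example_curve()
  mr_noisy <- mk$curve$mr * exp(withr::with_seed(8,
    rnorm(nrow(mk$curve), 0, 0.01)))
  curve <- tibble::tibble(t_s = mk$curve$t_s, mr = mr_noisy)
  fits <- suppressWarnings(
    purrr::map(thin_layer_models()$name,
               ~ tryCatch(fit_model(curve, .x, seed = 1),
                          error = function(e) NULL)))
  ranked <- select_best(purrr::compact(fits))
  expect_true("midilli_kucuk" %in% ranked$model[1:2])
})

test_that("fit_all_conditions covers the grid and records failures per cell", {
  gp <- generator_params()
  curves <- simulate_experiment(
    make_conditions_grid(c(40, 60), 0.3, 1500), gp)
  tbl <- fit_all_conditions(curves, models = c("newton", "page",
                                               "midilli_kucuk"),
                            seed = 1)
  expect_equal(nrow(tbl), 2 * 3)
  expect_true(all(tbl$converged))
  expect_true(all(tbl$r2 > 0.97))
  grid <- fit_report_grid(tbl)
  expect_equal(nrow(grid), 3)
  expect_equal(ncol(grid), 1 + 2 * 3) # model + (R2, chi2, RMSE) per condition

  # a curve too short for a 6-parameter model is recorded, not fatal
  short <- curves |>
    dplyr::group_by(condition_id) |>
    dplyr::slice_head(n = 6) |>
    dplyr::ungroup()
  cell <- fit_all_conditions(short, models = "modified_henderson_pabis")
  expect_true(all(!cell$converged))
  expect_true(all(!is.na(cell$error)))
})
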