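test_that("reversed min-max normalization matches its definition and inverts", {
  expect_equal(normalize_minmax(10, 0, 10), 0)  # x = xmax -> 0
  expect_equal(normalize_minmax(0, 0, 10), 1)   # x = xmin -> 1
  x <- runif(50, -3, 7)
  z <- normalize_minmax(x, -3, 7)
  expect_equal(denormalize_minmax(z, -3, 7), x, tolerance = 1e-12)
  zs <- normalize_minmax(x, -3, 7, method = "standard")
  expect_equal(zs, (x + 3) / 10)
  expect_equal(denormalize_minmax(zs, -3, 7, method = "standard"), x,
               tolerance = 1e-12)
  expect_error(normalize_minmax(1, 2, 2), class = "drykin_error_degenerate")
})

test_that("sigmoid satisfies its symmetry and saturation identities", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(50), 1, tolerance = 1e-12)
  expect_equal(sigmoid(2) + sigmoid(-2), 1, tolerance = 1e-12)
  expect_equal(sigmoid(-800), 0, tolerance = 1e-12) # no overflow
  x <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(sigmoid(x)) > 0))
})

test_that("analytic backprop gradients match central finite differences", {
  expect_lt(drykin:::mlp_gradient_check(c(3, 4, 1), activation = "sigmoid"),
            1e-6)
  expect_lt(drykin:::mlp_gradient_check(c(3, 5, 4, 1),
                                        activation = "sigmoid", seed = 7),
            1e-6)
})

test_that("seeded training is bit-reproducible, including with dropout", {
  d <- withr::with_seed(1, tibble::tibble(
    temperature_c = runif(40, 40, 60), velocity_ms = runif(40, 0.3, 1),
    intensity_wm2 = runif(40, 1500, 5500)))
  d$aw <- 0.45 - 1e-5 * (d$intensity_wm2 - 3500)
  m1 <- train_mlp(d, "aw", hidden = c(8, 8), epochs = 40, seed = 9)
  m2 <- train_mlp(d, "aw", hidden = c(8, 8), epochs = 40, seed = 9)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  m3 <- train_mlp(d, "aw", hidden = c(8, 8), epochs = 40, seed = 9,
                  dropout = 0.3)
  m4 <- train_mlp(d, "aw", hidden = c(8, 8), epochs = 40, seed = 9,
                  dropout = 0.3)
  expect_identical(m3$params, m4$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("the network learns a noiseless linear target to low test error", {
  d <- withr::with_seed(2, tibble::tibble(temperature_c = runif(200, 40, 60)))
  d$y <- 2 * (d$temperature_c - 40) / 20 + 3
  m <- train_mlp(d, "y", predictors = "temperature_c", hidden = c(15, 15),
                 activation = "relu", optimizer = "adam",
                 learning_rate = 0.01, epochs = 1000, seed = 5)
  expect_lt(m$metrics$rmse, 0.05)
  # averaged training loss decreases
  h <- m$history$loss
  expect_lt(mean(tail(h, 100)), mean(head(h, 100)))
})

test_that("divergent training fails loudly with its history attached", {
  d <- withr::with_seed(3, tibble::tibble(x = runif(50), y = runif(50)))
  expect_error(
    train_mlp(d, "y", predictors = "x", hidden = 5, optimizer = "sgd",
              learning_rate = 1e4, epochs = 50, seed = 1),
    class = "drykin_error_training")
})

test_that("cross-validation builds disjoint seeded folds consistent with the holdout", {
  d <- withr::with_seed(4, tibble::tibble(temperature_c = runif(200, 40, 60)))
  d$y <- 2 * (d$temperature_c - 40) / 20 + 3
  cv1 <- crossvalidate_mlp(d, "y", predictors = "temperature_c", k = 5,
                           hidden = c(10, 10), epochs = 300, seed = 2)
  expect_equal(cv1$n_test, rep(40, 5))
  cv2 <- crossvalidate_mlp(d, "y", predictors = "temperature_c", k = 5,
                           hidden = c(10, 10), epochs = 300, seed = 2)
  expect_identical(cv1, cv2)
  m <- train_mlp(d, "y", predictors = "temperature_c", hidden = c(10, 10),
                 epochs = 300, seed = 2)
  expect_lt(attr(cv1, "summary")$mean_rmse, 2 * max(m$metrics$rmse, 0.05))
  expect_error(crossvalidate_mlp(d[1:3, ], "y",
                                 predictors = "temperature_c", k = 5),
               class = "drykin_error_domain")
})

test_that("the RMSE metric is zero for perfect and SD-sized for constant predictions", {
  y <- withr::with_seed(6, runif(30))
  rmse <- function(m, p) sqrt(mean((m - p)^2))
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, rep(mean(y), 30)),
               sqrt(mean((y - mean(y))^2)), tolerance = 1e-12)
})
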