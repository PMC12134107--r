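## From-scratch feed-forward neural-network surrogate -------------------------
##
## Dense multilayer perceptron trained by backpropagation with SGD or Adam.
## Written in plain matrix algebra: the network, its gradients and the
## optimizers are part of the package's own method surface.

#' Logistic sigmoid activation
#'
#' `f(x) = 1 / (1 + exp(-x))`, computed in a saturation-safe form.
#'
#' @param x Numeric input, vectorised.
#' @return Values in (0, 1); `f(0) = 0.5`, `f(-x) = 1 - f(x)`.
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  dim(out) <- dim(x)
  out
}

relu <- function(x) pmax(x, 0)

#' Min-max normalization (reversed and standard forms)
#'
#' The default (`method = "printed"`) is the reversed min-max map
#' `X = (xmax - x) / (xmax - xmin)`, which sends `xmax` to 0 and `xmin` to 1;
#' `method = "standard"` is the conventional `(x - xmin) / (xmax - xmin)`.
#' Both map onto `[0, 1]` for `x` in `[xmin, xmax]` and invert exactly via
#' [denormalize_minmax()].
#'
#' @param x Numeric input.
#' @param xmin,xmax Feature bounds, `xmax > xmin`.
#' @param method `"printed"` (reversed) or `"standard"`.
#' @return Normalized values.
#' @export
normalize_minmax <- function(x, xmin = min(x), xmax = max(x),
                             method = c("printed", "standard")) {
  method <- match.arg(method)
  if (!is.finite(xmin) || !is.finite(xmax) || xmax <= xmin) {
    abort("Degenerate feature: need finite bounds with xmax > xmin.",
          class = "drykin_error_degenerate")
  }
  if (method == "printed") (xmax - x) / (xmax - xmin)
  else (x - xmin) / (xmax - xmin)
}

#' @rdname normalize_minmax
#' @param z Normalized values to invert.
#' @export
denormalize_minmax <- function(z, xmin, xmax,
                               method = c("printed", "standard")) {
  method <- match.arg(method)
  if (method == "printed") xmax - z * (xmax - xmin)
  else xmin + z * (xmax - xmin)
}

## Weight init: scaled uniform by fan-in, biases zero. Call inside a seeded
## context.
mlp_init <- function(layer_sizes) {
  n_layers <- length(layer_sizes) - 1
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- layer_sizes[l]
    s <- 1 / sqrt(fan_in)
    W[[l]] <- matrix(runif(fan_in * layer_sizes[l + 1], -s, s),
                     fan_in, layer_sizes[l + 1])
    b[[l]] <- rep(0, layer_sizes[l + 1])
  }
  list(W = W, b = b)
}

activate <- function(z, activation) {
  switch(activation, relu = relu(z), sigmoid = sigmoid(z),
         abort(sprintf("Unknown activation '%s'.", activation),
               class = "drykin_error_domain"))
}

activate_grad <- function(z, a, activation) {
  switch(activation,
         relu = (z > 0) * 1,
         sigmoid = a * (1 - a))
}

## Forward pass. Output layer is linear (regression). `masks` are inverted
## dropout masks for the hidden layers (already scaled by 1/keep), or NULL.
mlp_forward <- function(params, X, activation, masks = NULL) {
  L <- length(params$W)
  Z <- vector("list", L)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    if (l < L) {
      A[[l + 1]] <- activate(Z[[l]], activation)
      if (!is.null(masks)) A[[l + 1]] <- A[[l + 1]] * masks[[l]]
    } else {
      A[[l + 1]] <- Z[[l]]
    }
  }
  list(Z = Z, A = A)
}

## Mean-squared-error loss and its analytic gradients via backpropagation.
mlp_loss_grads <- function(params, X, Y, activation, masks = NULL) {
  L <- length(params$W)
  fw <- mlp_forward(params, X, activation, masks)
  pred <- fw$A[[L + 1]]
  n <- length(Y)
  loss <- sum((pred - Y)^2) / n
  delta <- 2 * (pred - Y) / n
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params$W[[l]])
      g <- activate_grad(fw$Z[[l - 1]], fw$A[[l]], activation)
      ## fw$A[[l]] is post-dropout; for relu the gradient uses Z only, for
      ## sigmoid recompute the clean activation
      if (activation == "sigmoid") g <- {
        a_clean <- sigmoid(fw$Z[[l - 1]])
        a_clean * (1 - a_clean)
      }
      delta <- delta * g
      if (!is.null(masks)) delta <- delta * masks[[l - 1]]
    }
  }
  list(loss = loss, gW = gW, gb = gb, pred = pred)
}

## One optimizer step; state carries Adam moments.
optimizer_step <- function(params, grads, state, optimizer, lr) {
  L <- length(params$W)
  if (optimizer == "sgd") {
    for (l in seq_len(L)) {
      params$W[[l]] <- params$W[[l]] - lr * grads$gW[[l]]
      params$b[[l]] <- params$b[[l]] - lr * grads$gb[[l]]
    }
    return(list(params = params, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1
  for (l in seq_len(L)) {
    state$mW[[l]] <- b1 * state$mW[[l]] + (1 - b1) * grads$gW[[l]]
    state$vW[[l]] <- b2 * state$vW[[l]] + (1 - b2) * grads$gW[[l]]^2
    state$mb[[l]] <- b1 * state$mb[[l]] + (1 - b1) * grads$gb[[l]]
    state$vb[[l]] <- b2 * state$vb[[l]] + (1 - b2) * grads$gb[[l]]^2
    mW_hat <- state$mW[[l]] / (1 - b1^state$t)
    vW_hat <- state$vW[[l]] / (1 - b2^state$t)
    mb_hat <- state$mb[[l]] / (1 - b1^state$t)
    vb_hat <- state$vb[[l]] / (1 - b2^state$t)
    params$W[[l]] <- params$W[[l]] - lr * mW_hat / (sqrt(vW_hat) + eps)
    params$b[[l]] <- params$b[[l]] - lr * mb_hat / (sqrt(vb_hat) + eps)
  }
  list(params = params, state = state)
}

new_adam_state <- function(params) {
  zero_like <- function(x) {
    purrr::map(x, ~ if (is.matrix(.x)) matrix(0, nrow(.x), ncol(.x))
               else rep(0, length(.x)))
  }
  list(t = 0, mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b))
}

## Core training loop on a fixed design matrix. Must be called inside a
## seeded context; returns params, history and final normalized-scale loss.
mlp_train_core <- function(X, Y, hidden, activation, optimizer, lr, epochs,
                           batch_size, dropout) {
  n <- nrow(X)
  params <- mlp_init(c(ncol(X), hidden, ncol(Y)))
  state <- if (optimizer == "adam") new_adam_state(params)
  history <- numeric(epochs)
  keep <- 1 - dropout
  n_hidden <- length(hidden)
  for (epoch in seq_len(epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    for (batch in batches) {
      masks <- if (dropout > 0) {
        purrr::map(seq_len(n_hidden), function(l) {
          matrix(stats::rbinom(length(batch) * hidden[l], 1, keep) / keep,
                 length(batch), hidden[l])
        })
      }
      grads <- mlp_loss_grads(params, X[batch, , drop = FALSE],
                              Y[batch, , drop = FALSE], activation, masks)
      stepped <- optimizer_step(params, grads, state, optimizer, lr)
      params <- stepped$params
      state <- stepped$state
    }
    fw <- mlp_forward(params, X, activation)
    history[epoch] <- sum((fw$A[[length(params$W) + 1]] - Y)^2) / length(Y)
    if (!is.finite(history[epoch])) {
      abort("Training diverged (loss is not finite).",
            class = "drykin_error_training",
            history = history[seq_len(epoch)])
    }
  }
  list(params = params, history = history)
}

#' Train a feed-forward neural-network surrogate
#'
#' Trains a dense multilayer perceptron mapping drying conditions to a
#' quality response by backpropagation. Features and target are min-max
#' normalized (reversed form by default, see [normalize_minmax()]); the
#' output layer is linear and predictions are returned on the original
#' scale. The dataset is randomly split 70/30 into training and test rows,
#' and test RMSE (`sqrt(mean((measured - predicted)^2))`) and R2 are
#' reported on the original scale. Training is bit-reproducible given the
#' seed.
#'
#' @param data Tibble with predictor and response columns; >= 10 rows.
#' @param response Name of the response column.
#' @param predictors Names of the predictor columns (default: the three
#'   process variables).
#' @param hidden Integer vector of hidden-layer widths (1-3 layers typical).
#' @param activation `"relu"` or `"sigmoid"` (hidden layers).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Optimizer step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param dropout Hidden-layer dropout rate in `[0, 1)` (inverted dropout,
#'   training time only).
#' @param train_fraction Fraction of rows used for training, in (0, 1).
#' @param normalization Min-max form, `"printed"` (reversed) or
#'   `"standard"`.
#' @param seed Integer seed covering the split, weight init, shuffling and
#'   dropout.
#' @return A `trained_mlp` object: weights, normalization bounds, training
#'   history tibble, and test `metrics` tibble (`rmse`, `r2`, `n_train`,
#'   `n_test`).
#' @export
train_mlp <- function(data, response,
                      predictors = c("temperature_c", "velocity_ms",
                                     "intensity_wm2"),
                      hidden = c(15, 15),
                      activation = c("relu", "sigmoid"),
                      optimizer = c("adam", "sgd"),
                      learning_rate = 0.01, epochs = 500, batch_size = 16,
                      dropout = 0, train_fraction = 0.7,
                      normalization = c("printed", "standard"),
                      seed = 1L) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  normalization <- match.arg(normalization)
  check_columns(data, c(response, predictors))
  stopifnot(train_fraction > 0, train_fraction < 1, learning_rate > 0,
            all(hidden >= 1), dropout >= 0, dropout < 1)
  if (nrow(data) < 10) {
    abort("Need >= 10 rows to train.", class = "drykin_error_domain")
  }
  raw_x <- as.matrix(data[, predictors])
  raw_y <- as.matrix(data[, response])
  if (any(!is.finite(raw_x)) || any(!is.finite(raw_y))) {
    abort("Features and target must be finite.",
          class = "drykin_error_domain")
  }
  bounds_x <- purrr::map(predictors, ~ range(raw_x[, .x]))
  names(bounds_x) <- predictors
  bounds_y <- range(raw_y)
  X <- vapply(predictors, function(p) {
    normalize_minmax(raw_x[, p], bounds_x[[p]][1], bounds_x[[p]][2],
                     normalization)
  }, numeric(nrow(raw_x)))
  Y <- matrix(normalize_minmax(raw_y[, 1], bounds_y[1], bounds_y[2],
                               normalization), ncol = 1)

  n <- nrow(X)
  result <- withr::with_seed(seed, {
    train_idx <- sort(sample.int(n, floor(train_fraction * n)))
    core <- mlp_train_core(X[train_idx, , drop = FALSE],
                           Y[train_idx, , drop = FALSE],
                           hidden, activation, optimizer, learning_rate,
                           epochs, batch_size, dropout)
    list(train_idx = train_idx, core = core)
  })
  obj <- structure(
    list(params = result$core$params, hidden = hidden,
         activation = activation, optimizer = optimizer,
         learning_rate = learning_rate, dropout = dropout,
         predictors = predictors, response = response,
         normalization = normalization, bounds_x = bounds_x,
         bounds_y = bounds_y,
         history = tibble::tibble(epoch = seq_along(result$core$history),
                                  loss = result$core$history),
         train_idx = result$train_idx, seed = as.integer(seed)),
    class = "trained_mlp"
  )
  test_idx <- setdiff(seq_len(n), result$train_idx)
  pred_test <- predict(obj, data[test_idx, ])
  y_test <- raw_y[test_idx, 1]
  ss_tot <- sum((y_test - mean(y_test))^2)
  obj$metrics <- tibble::tibble(
    rmse = sqrt(mean((y_test - pred_test)^2)),
    r2 = if (ss_tot > 0) 1 - sum((y_test - pred_test)^2) / ss_tot
         else NA_real_,
    n_train = length(result$train_idx),
    n_test = length(test_idx)
  )
  obj
}

#' @export
predict.trained_mlp <- function(object, newdata, ...) {
  check_columns(newdata, object$predictors, arg = "newdata")
  X <- vapply(object$predictors, function(p) {
    normalize_minmax(newdata[[p]], object$bounds_x[[p]][1],
                     object$bounds_x[[p]][2], object$normalization)
  }, numeric(nrow(newdata)))
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(newdata))
  fw <- mlp_forward(object$params, X, object$activation)
  z <- fw$A[[length(object$params$W) + 1]][, 1]
  denormalize_minmax(z, object$bounds_y[1], object$bounds_y[2],
                     object$normalization)
}

#' @export
print.trained_mlp <- function(x, ...) {
  cat(sprintf("<trained_mlp> %s ~ %s\n", x$response,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  hidden: %s | %s + %s | lr %.3g | dropout %.2g\n",
              paste(x$hidden, collapse = "x"), x$activation, x$optimizer,
              x$learning_rate, x$dropout))
  cat(sprintf("  test RMSE = %.4g, R2 = %.4f (train %d / test %d)\n",
              x$metrics$rmse, x$metrics$r2, x$metrics$n_train,
              x$metrics$n_test))
  invisible(x)
}

#' @rdname train_mlp
#' @param x,object A `trained_mlp`.
#' @param ... Unused.
#' @export
glance.trained_mlp <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(response = x$response,
                   architecture = paste(x$hidden, collapse = "x"),
                   activation = x$activation, optimizer = x$optimizer),
    x$metrics
  )
}

#' k-fold cross-validation of the neural surrogate
#'
#' Splits the rows into `k` disjoint folds by a seeded shuffle, trains on
#' k-1 folds and evaluates RMSE / R2 on the held-out fold, for each fold in
#' turn. Hyperparameters are passed through to the training core.
#'
#' @inheritParams train_mlp
#' @param k Number of folds (`<= nrow(data)`).
#' @return A tibble with one row per fold (`fold`, `n_test`, `rmse`, `r2`)
#'   and a `summary` attribute holding mean and SD of both metrics.
#' @export
crossvalidate_mlp <- function(data, response,
                              predictors = c("temperature_c", "velocity_ms",
                                             "intensity_wm2"),
                              k = 5, hidden = c(15, 15),
                              activation = c("relu", "sigmoid"),
                              optimizer = c("adam", "sgd"),
                              learning_rate = 0.01, epochs = 500,
                              batch_size = 16, dropout = 0,
                              normalization = c("printed", "standard"),
                              seed = 1L) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  normalization <- match.arg(normalization)
  check_columns(data, c(response, predictors))
  n <- nrow(data)
  if (k > n) {
    abort("More folds than rows.", class = "drykin_error_domain")
  }
  fold_of <- withr::with_seed(seed,
                              sample(rep(seq_len(k), length.out = n)))
  rows <- purrr::map(seq_len(k), function(fold) {
    test_idx <- which(fold_of == fold)
    train_data <- data[-test_idx, ]
    raw_x <- as.matrix(train_data[, predictors])
    raw_y <- train_data[[response]]
    bounds_x <- purrr::map(predictors, ~ range(raw_x[, .x]))
    names(bounds_x) <- predictors
    bounds_y <- range(raw_y)
    X <- vapply(predictors, function(p) {
      normalize_minmax(raw_x[, p], bounds_x[[p]][1], bounds_x[[p]][2],
                       normalization)
    }, numeric(nrow(raw_x)))
    Y <- matrix(normalize_minmax(raw_y, bounds_y[1], bounds_y[2],
                                 normalization), ncol = 1)
    core <- withr::with_seed(
      seed + fold,
      mlp_train_core(X, Y, hidden, activation, optimizer, learning_rate,
                     epochs, batch_size, dropout))
    Xt <- vapply(predictors, function(p) {
      normalize_minmax(data[[p]][test_idx], bounds_x[[p]][1],
                       bounds_x[[p]][2], normalization)
    }, numeric(length(test_idx)))
    if (!is.matrix(Xt)) Xt <- matrix(Xt, nrow = length(test_idx))
    fw <- mlp_forward(core$params, Xt, activation)
    pred <- denormalize_minmax(fw$A[[length(core$params$W) + 1]][, 1],
                               bounds_y[1], bounds_y[2], normalization)
    y_test <- data[[response]][test_idx]
    ss_tot <- sum((y_test - mean(y_test))^2)
    tibble::tibble(
      fold = fold, n_test = length(test_idx),
      rmse = sqrt(mean((y_test - pred)^2)),
      r2 = if (ss_tot > 0) 1 - sum((y_test - pred)^2) / ss_tot
           else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- tibble::tibble(
    mean_rmse = mean(out$rmse), sd_rmse = sd(out$rmse),
    mean_r2 = mean(out$r2), sd_r2 = sd(out$r2)
  )
  out
}

## Central finite-difference gradient of the MLP loss, for verifying the
## analytic backpropagation. Returns the largest relative discrepancy.
mlp_gradient_check <- function(layer_sizes = c(3, 4, 1), n_rows = 7,
                               activation = "sigmoid", eps = 1e-6,
                               seed = 42L) {
  withr::with_seed(seed, {
    params <- mlp_init(layer_sizes)
    X <- matrix(runif(n_rows * layer_sizes[1]), n_rows)
    Y <- matrix(runif(n_rows), n_rows, 1)
  })
  analytic <- mlp_loss_grads(params, X, Y, activation)
  worst <- 0
  for (l in seq_along(params$W)) {
    for (what in c("W", "b")) {
      theta <- params[[what]][[l]]
      g_ana <- if (what == "W") analytic$gW[[l]] else analytic$gb[[l]]
      for (i in seq_along(theta)) {
        bump <- function(h) {
          p2 <- params
          p2[[what]][[l]][i] <- theta[i] + h
          mlp_loss_grads(p2, X, Y, activation)$loss
        }
        g_num <- (bump(eps) - bump(-eps)) / (2 * eps)
        denom <- max(abs(g_num), abs(g_ana[i]), 1e-8)
        worst <- max(worst, abs(g_num - g_ana[i]) / denom)
      }
    }
  }
  worst
}
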