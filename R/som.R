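## Kohonen self-organizing map ------------------------------------------------
##
## Online competitive learning on a rectangular grid (20 x 20 by default,
## i.e. 400 units), with linearly decaying learning rate and Gaussian
## neighbourhood. Codebook units are grouped into a small number of clusters
## by agglomerative (Ward) clustering.

#' Train a self-organizing map over drying conditions and quality outputs
#'
#' Features are min-max normalized (reversed form by default), codebook
#' vectors are seeded-uniform initialised, and the map is trained online:
#' for each presented row the best-matching unit (BMU) and its Gaussian
#' neighbourhood move toward the row, with learning rate and neighbourhood
#' radius decaying linearly across epochs. Quantization error (mean distance
#' of rows to their BMU) is recorded after every epoch. Codebook vectors are
#' finally grouped into `n_clusters` clusters by Ward agglomeration.
#'
#' @param data Tibble with the feature columns; >= 10 rows.
#' @param columns Feature column names (default: process variables).
#' @param grid_dim Map dimensions, default `c(20, 20)` (400 units).
#' @param epochs Training epochs (full passes over the data).
#' @param alpha Length-2 learning-rate schedule (start, end).
#' @param radius Length-2 neighbourhood-radius schedule (start, end);
#'   default starts at a third of the larger grid side and ends at 0.5.
#' @param n_clusters Number of codebook clusters.
#' @param normalization Min-max form (see [normalize_minmax()]).
#' @param seed Integer seed covering initialisation and presentation order.
#' @return A `som_fit` with `codebook` (units x features, original scale in
#'   `codebook_raw`), `unit_coords`, `qe` (per-epoch quantization error),
#'   `unit_cluster`, and `assignments` (per-row `bmu` and `cluster`).
#' @export
train_som <- function(data,
                      columns = c("temperature_c", "velocity_ms",
                                  "intensity_wm2"),
                      grid_dim = c(20, 20), epochs = 10,
                      alpha = c(0.5, 0.01), radius = NULL, n_clusters = 5,
                      normalization = c("printed", "standard"),
                      seed = 1L) {
  normalization <- match.arg(normalization)
  check_columns(data, columns)
  stopifnot(length(grid_dim) == 2, all(grid_dim >= 1), epochs >= 1,
            n_clusters >= 1)
  if (nrow(data) < 10) {
    abort("Need >= 10 rows to train a map.", class = "drykin_error_domain")
  }
  raw <- as.matrix(data[, columns])
  if (any(!is.finite(raw))) {
    abort("Features must be finite.", class = "drykin_error_domain")
  }
  bounds <- purrr::map(columns, ~ range(raw[, .x]))
  names(bounds) <- columns
  X <- vapply(columns, function(p) {
    normalize_minmax(raw[, p], bounds[[p]][1], bounds[[p]][2], normalization)
  }, numeric(nrow(raw)))

  n_units <- prod(grid_dim)
  coords <- as.matrix(tidyr::expand_grid(gx = seq_len(grid_dim[1]),
                                         gy = seq_len(grid_dim[2])))
  radius <- radius %||% c(max(grid_dim) / 3, 0.5)
  n <- nrow(X)

  result <- withr::with_seed(seed, {
    codebook <- matrix(runif(n_units * ncol(X)), n_units, ncol(X))
    qe <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      frac <- if (epochs == 1) 0 else (epoch - 1) / (epochs - 1)
      a <- alpha[1] + frac * (alpha[2] - alpha[1])
      r <- radius[1] + frac * (radius[2] - radius[1])
      for (i in sample.int(n)) {
        x <- X[i, ]
        d2 <- rowSums(sweep(codebook, 2, x)^2)
        bmu <- which.min(d2)
        gd2 <- (coords[, 1] - coords[bmu, 1])^2 +
          (coords[, 2] - coords[bmu, 2])^2
        h <- a * exp(-gd2 / (2 * r^2))
        codebook <- codebook + h * sweep(-codebook, 2, x, "+")
      }
      qe[epoch] <- mean(vapply(seq_len(n), function(i) {
        sqrt(min(rowSums(sweep(codebook, 2, X[i, ])^2)))
      }, numeric(1)))
    }
    list(codebook = codebook, qe = qe)
  })
  codebook <- result$codebook
  unit_cluster <- if (n_clusters > 1) {
    cutree(hclust(dist(codebook), method = "ward.D2"), k = n_clusters)
  } else {
    rep(1L, n_units)
  }
  bmu <- vapply(seq_len(n), function(i) {
    which.min(rowSums(sweep(codebook, 2, X[i, ])^2))
  }, integer(1))
  codebook_raw <- vapply(seq_along(columns), function(j) {
    denormalize_minmax(codebook[, j], bounds[[j]][1], bounds[[j]][2],
                       normalization)
  }, numeric(n_units))
  colnames(codebook_raw) <- columns
  structure(
    list(codebook = codebook, codebook_raw = codebook_raw,
         unit_coords = tibble::tibble(unit = seq_len(n_units),
                                      gx = coords[, 1], gy = coords[, 2],
                                      cluster = unit_cluster),
         grid_dim = grid_dim, columns = columns, bounds = bounds,
         normalization = normalization,
         qe = tibble::tibble(epoch = seq_len(epochs),
                             quantization_error = result$qe),
         unit_cluster = unit_cluster,
         assignments = tibble::tibble(row = seq_len(n), bmu = bmu,
                                      cluster = unit_cluster[bmu]),
         n_clusters = as.integer(n_clusters), seed = as.integer(seed)),
    class = "som_fit"
  )
}

#' Assign new rows to a trained map
#'
#' @param fit A `som_fit`.
#' @param data Tibble containing the map's feature columns.
#' @return Tibble with `row`, `bmu`, `cluster`, `distance`.
#' @export
som_assign <- function(fit, data) {
  stopifnot(inherits(fit, "som_fit"))
  check_columns(data, fit$columns)
  X <- vapply(fit$columns, function(p) {
    normalize_minmax(data[[p]], fit$bounds[[p]][1], fit$bounds[[p]][2],
                     fit$normalization)
  }, numeric(nrow(data)))
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(data))
  res <- purrr::map_dfr(seq_len(nrow(X)), function(i) {
    d2 <- rowSums(sweep(fit$codebook, 2, X[i, ])^2)
    bmu <- which.min(d2)
    tibble::tibble(row = i, bmu = bmu,
                   cluster = fit$unit_cluster[bmu],
                   distance = sqrt(d2[bmu]))
  })
  res
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("<som_fit> %d x %d map (%d units), %d clusters\n",
              x$grid_dim[1], x$grid_dim[2], prod(x$grid_dim),
              x$n_clusters))
  cat(sprintf("  features: %s\n", paste(x$columns, collapse = ", ")))
  cat(sprintf("  quantization error: %.4g (epoch 1) -> %.4g (final)\n",
              x$qe$quantization_error[1],
              tail(x$qe$quantization_error, 1)))
  invisible(x)
}

#' @rdname train_som
#' @param x A `som_fit`.
#' @param ... Unused.
#' @export
glance.som_fit <- function(x, ...) {
  tibble::tibble(
    n_units = prod(x$grid_dim), n_clusters = x$n_clusters,
    epochs = nrow(x$qe),
    qe_first = x$qe$quantization_error[1],
    qe_final = tail(x$qe$quantization_error, 1)
  )
}
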