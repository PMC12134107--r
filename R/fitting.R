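## Nonlinear least-squares fitting of thin-layer models -----------------------

#' Goodness-of-fit statistics for a drying-curve fit
#'
#' Computes the three statistics used to compare thin-layer models: the
#' coefficient of determination `R2 = 1 - SSres/SStot`, the reduced
#' chi-square `chi2 = SSres / (N - n)` and the root mean square error
#' `RMSE = sqrt(SSres / N)`, where N is the number of observations and n the
#' number of fitted parameters.
#'
#' @param observed,predicted Equal-length numeric vectors of moisture ratios.
#' @param n_params Number of fitted parameters, `< length(observed)`.
#' @return A one-row tibble with `r2`, `chi2`, `rmse`, `n_obs`, `n_params`.
#' @examples
#' goodness(c(1, 0.5), c(0.9, 0.6), n_params = 1) # rmse 0.1, chi2 0.02
#' @export
goodness <- function(observed, predicted, n_params) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.",
          class = "drykin_error_domain")
  }
  n_obs <- length(observed)
  if (n_obs <= n_params) {
    abort("Need more observations than parameters.",
          class = "drykin_error_domain")
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) {
    abort("R2 is undefined for zero-variance observations.",
          class = "drykin_error_degenerate")
  }
  tibble::tibble(
    r2 = 1 - ss_res / ss_tot,
    chi2 = ss_res / (n_obs - n_params),
    rmse = sqrt(ss_res / n_obs),
    n_obs = n_obs,
    n_params = as.integer(n_params)
  )
}

## Initial rate constant from the slope of ln(MR) vs t. MR readings above 1
## (noise) are clipped to a 1.05 ceiling for this ln-based step only.
init_rate_constant <- function(t, mr) {
  keep <- mr > 0
  y <- log(pmin(mr[keep], 1.05))
  slope <- coef(lm(y ~ t[keep]))[[2]]
  k0 <- max(-slope, 1e-7)
  min(max(k0, 1.1e-8), 0.99)
}

canonical_start <- function(model_name, params, k0) {
  start <- numeric(length(params))
  names(start) <- params
  for (p in params) {
    start[[p]] <- switch(
      p,
      k = k0, k0 = k0, n = 1, b = 0, c = 0,
      g = max(k0 * 0.3, 1.1e-8), h = min(max(k0 * 3, 1.1e-8), 0.99),
      k1 = max(k0 * 0.3, 1.1e-8),
      a = 1
    )
  }
  ## multi-exponential amplitudes summing to one to keep MR(0) = 1
  if (model_name == "verma") start[["a"]] <- 0.7
  if (model_name == "two_term") {
    start[["a"]] <- 0.7
    start[["b"]] <- 0.3
  }
  if (model_name == "modified_henderson_pabis") {
    start[["a"]] <- 0.5
    start[["b"]] <- 0.3
    start[["c"]] <- 0.2
  }
  if (model_name == "wang_singh") {
    start[["a"]] <- -k0
    start[["b"]] <- k0^2 / 4
  }
  start
}

clamp_to_bounds <- function(start, bounds) {
  for (p in names(start)) {
    lo <- bounds[[p]][1]
    hi <- bounds[[p]][2]
    eps <- 1e-12 * max(1, abs(hi - lo))
    start[[p]] <- min(max(start[[p]], lo + eps), hi - eps)
  }
  start
}

jitter_start <- function(start, bounds) {
  out <- start
  for (p in names(out)) {
    if (p %in% RATE_PARAMS) {
      out[[p]] <- out[[p]] * exp(rnorm(1, 0, 0.7))
    } else if (p == "n") {
      out[[p]] <- out[[p]] * exp(rnorm(1, 0, 0.2))
    } else {
      out[[p]] <- out[[p]] + rnorm(1, 0, 0.2)
    }
  }
  clamp_to_bounds(out, bounds)
}

## Closed-form linear least squares for the Thomson inverse model:
## t = a y + b y^2 with y = ln(MR). Report statistics are computed in
## MR-space after inversion so all models share one scale.
fit_thomson <- function(t, mr) {
  y <- log(mr)
  X <- cbind(y, y^2)
  cf <- stats::lm.fit(X, t)$coefficients
  params <- c(a = unname(cf[1]), b = unname(cf[2]))
  if (!is.finite(params[["b"]])) params[["b"]] <- 0
  resid_t <- t - (params[["a"]] * y + params[["b"]] * y^2)
  pred_mr <- tryCatch(thomson_predict_mr(params, t), error = function(e) NULL)
  list(params = params, pred = pred_mr,
       rmse_t = sqrt(mean(resid_t^2)), converged = !is.null(pred_mr),
       iterations = 0L)
}

#' Fit one thin-layer model to a drying curve
#'
#' Minimises the sum of squared moisture-ratio residuals by
#' Levenberg-Marquardt with multi-start initialisation: the first start sets
#' rate constants from the slope of `ln(MR)` vs `t`, amplitudes at their
#' canonical values and shape/offset terms at their identity values; the
#' remaining starts are seeded jitters of it. Wang-Singh and Thomson are
#' linear in their parameters and solved in closed form (Thomson in t-space,
#' its stated form, with report statistics computed in MR-space after
#' inversion).
#'
#' @param curve Tibble with columns `t_s` and `mr` (one condition).
#' @param model Model name or registry row.
#' @param n_starts Number of multi-start initialisations (>= 1).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param seed Seed for the jittered starts; fits are deterministic given it.
#' @param bounds Optional named list of `(lo, hi)` overriding the registry
#'   defaults.
#' @return A `thin_layer_fit` object with elements `model`, `label`,
#'   `parameters`, `stats` (see [goodness()]), `converged`, `iterations`,
#'   `fitted`, `residuals`, `data` and, for Thomson, `rmse_t`.
#' @export
fit_model <- function(curve, model, n_starts = 5, max_iter = 1000,
                      seed = 1L, bounds = NULL) {
  model <- get_model(model)
  check_columns(curve, c("t_s", "mr"), arg = "curve")
  t <- curve$t_s
  mr <- curve$mr
  bad <- !is.finite(mr) | mr <= 0 | mr > 1.05
  if (any(bad)) {
    warn(sprintf("Dropping %d observation(s) with MR outside (0, 1.05].",
                 sum(bad)))
    t <- t[!bad]
    mr <- mr[!bad]
  }
  params <- model$params[[1]]
  if (length(mr) < length(params) + 2) {
    abort(sprintf("Model '%s' needs at least %d usable points.",
                  model$name, length(params) + 2),
          class = "drykin_error_domain")
  }
  if (sd(mr) < 1e-12) {
    abort("Degenerate curve: moisture ratio is constant.",
          class = "drykin_error_degenerate")
  }
  bnds <- model$bounds[[1]]
  if (!is.null(bounds)) bnds[names(bounds)] <- bounds

  if (model$name == "thomson") {
    th <- fit_thomson(t, mr)
    stats <- if (th$converged) {
      goodness(mr, th$pred, length(params))
    } else {
      tibble::tibble(r2 = NA_real_, chi2 = NA_real_, rmse = NA_real_,
                     n_obs = length(mr), n_params = length(params))
    }
    return(new_thin_layer_fit(model, th$params, stats, th$converged,
                              th$iterations, th$pred, t, mr,
                              rmse_t = th$rmse_t))
  }

  if (model$name == "wang_singh") {
    cf <- stats::lm.fit(cbind(t, t^2), mr - 1)$coefficients
    pars <- clamp_to_bounds(c(a = unname(cf[1]), b = unname(cf[2])), bnds)
    pred <- mr_wang_singh(t, as.list(pars))
    return(new_thin_layer_fit(model, pars, goodness(mr, pred, 2), TRUE, 0L,
                              pred, t, mr))
  }

  k0 <- init_rate_constant(t, mr)
  start0 <- clamp_to_bounds(canonical_start(model$name, params, k0), bnds)
  starts <- c(
    list(start0),
    if (n_starts > 1) {
      withr::with_seed(seed, purrr::map(seq_len(n_starts - 1),
                                        ~ jitter_start(start0, bnds)))
    }
  )
  lower <- vapply(params, function(p) bnds[[p]][1], numeric(1))
  upper <- vapply(params, function(p) bnds[[p]][2], numeric(1))
  fun <- model$fun[[1]]
  resid_fn <- function(par) {
    r <- fun(t, as.list(par)) - mr
    r[!is.finite(r)] <- 1e6
    r
  }
  runs <- purrr::map(starts, function(s) {
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par = s, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = min(max_iter, 1024), ftol = 1e-15, ptol = 1e-15)
      )
      list(par = coef(fit), ssr = fit$deviance, niter = fit$niter,
           converged = fit$info %in% 1:4)
    }, error = function(e) NULL)
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0) {
    abort(sprintf("All starts failed for model '%s'.", model$name),
          class = "drykin_error_fit")
  }
  best <- runs[[which.min(purrr::map_dbl(runs, "ssr"))]]
  pred <- fun(t, as.list(best$par))
  new_thin_layer_fit(model, best$par, goodness(mr, pred, length(params)),
                     best$converged, as.integer(best$niter), pred, t, mr)
}

new_thin_layer_fit <- function(model, parameters, stats, converged,
                               iterations, fitted, t, mr, rmse_t = NULL) {
  structure(
    list(model = model$name, label = model$label,
         parameters = parameters, stats = stats,
         converged = converged, iterations = iterations,
         fitted = fitted, residuals = if (!is.null(fitted)) mr - fitted,
         data = tibble::tibble(t_s = t, mr = mr), rmse_t = rmse_t),
    class = "thin_layer_fit"
  )
}

#' @export
print.thin_layer_fit <- function(x, ...) {
  cat(sprintf("<thin_layer_fit> %s (%s)\n", x$label,
              if (x$converged) "converged" else "NOT converged"))
  cat("  parameters:",
      paste(sprintf("%s = %.6g", names(x$parameters), x$parameters),
            collapse = ", "), "\n")
  cat(sprintf("  R2 = %.5f  chi2 = %.3e  RMSE = %.3e  (N = %d)\n",
              x$stats$r2, x$stats$chi2, x$stats$rmse, x$stats$n_obs))
  invisible(x)
}

#' @rdname fit_model
#' @param x,object A `thin_layer_fit`.
#' @param ... Unused.
#' @export
tidy.thin_layer_fit <- function(x, ...) {
  tibble::tibble(model = x$model, term = names(x$parameters),
                 estimate = unname(x$parameters))
}

#' @rdname fit_model
#' @export
glance.thin_layer_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$model, converged = x$converged,
                   iterations = x$iterations),
    x$stats
  )
}

#' Rank thin-layer fits by the three-metric rule
#'
#' Ranks candidate fits of the same curve by the mean of three ranks:
#' R2 descending, chi-square ascending, RMSE ascending. Ties are broken by
#' fewer parameters, then by model name.
#'
#' @param results A list of `thin_layer_fit` objects, or a tibble with
#'   columns `model`, `r2`, `chi2`, `rmse`, `n_params` (and optionally
#'   `converged`).
#' @return A tibble of converged fits ordered by rank, with `rank` and
#'   `rank_score` columns.
#' @export
select_best <- function(results) {
  tbl <- if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    purrr::map_dfr(results, glance)
  }
  check_columns(tbl, c("model", "r2", "chi2", "rmse", "n_params"),
                arg = "results")
  if (!"converged" %in% names(tbl)) tbl$converged <- TRUE
  tbl <- dplyr::filter(tbl, .data$converged, is.finite(.data$r2),
                       is.finite(.data$chi2), is.finite(.data$rmse))
  if (nrow(tbl) == 0) {
    abort("No converged fits to rank.", class = "drykin_error_selection")
  }
  tbl <- dplyr::mutate(
    tbl,
    rank_score = (rank(-.data$r2, ties.method = "average") +
                    rank(.data$chi2, ties.method = "average") +
                    rank(.data$rmse, ties.method = "average")) / 3
  )
  tbl <- dplyr::arrange(tbl, .data$rank_score, .data$n_params, .data$model)
  dplyr::mutate(tbl, rank = dplyr::row_number(), .before = 1)
}

#' Fit a set of models to every condition in a dataset
#'
#' @param curves Long tibble of drying curves with `condition_id`, `t_s`,
#'   `mr` columns (see [simulate_experiment()]).
#' @param models Character vector of model names; `NULL` fits all eleven.
#' @param ... Passed to [fit_model()] (`n_starts`, `max_iter`, `seed`).
#' @param keep_fits Keep the full fit objects in a list column?
#' @return A tibble with one row per (condition, model): fitted parameter
#'   list column, `r2`, `chi2`, `rmse`, `converged`, and `error` (message for
#'   cells whose fit failed; such failures are recorded, not fatal).
#' @export
fit_all_conditions <- function(curves, models = NULL, ...,
                               keep_fits = FALSE) {
  check_columns(curves, c("condition_id", "t_s", "mr"))
  if (nrow(curves) == 0) {
    abort("`curves` is empty.", class = "drykin_error_domain")
  }
  models <- models %||% thin_layer_models()$name
  grid <- tidyr::expand_grid(
    condition_id = unique(curves$condition_id),
    model = models
  )
  rows <- purrr::pmap(grid, function(condition_id, model) {
    curve <- curves[curves$condition_id == condition_id, ]
    fit <- tryCatch(fit_model(curve, model, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(
        condition_id = condition_id, model = model,
        params = list(NULL), n_params = NA_integer_, r2 = NA_real_,
        chi2 = NA_real_, rmse = NA_real_, converged = FALSE,
        error = conditionMessage(fit),
        fit = if (keep_fits) list(NULL)
      )
    } else {
      tibble::tibble(
        condition_id = condition_id, model = model,
        params = list(fit$parameters), n_params = fit$stats$n_params,
        r2 = fit$stats$r2, chi2 = fit$stats$chi2, rmse = fit$stats$rmse,
        converged = fit$converged, error = NA_character_,
        fit = if (keep_fits) list(fit)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  cond_cols <- intersect(c("temperature_c", "velocity_ms", "intensity_wm2"),
                         names(curves))
  if (length(cond_cols) > 0) {
    key <- dplyr::distinct(
      curves, dplyr::across(dplyr::all_of(c("condition_id", cond_cols))))
    out <- dplyr::left_join(out, key, by = "condition_id")
  }
  out
}

#' Reshape per-condition fit results into a models-by-conditions grid
#'
#' Produces the wide report layout customary for thin-layer drying studies:
#' one row per model, one column group (R2, chi2, RMSE) per condition.
#'
#' @param fit_tbl Output of [fit_all_conditions()].
#' @return A wide tibble, models as rows.
#' @export
fit_report_grid <- function(fit_tbl) {
  check_columns(fit_tbl, c("condition_id", "model", "r2", "chi2", "rmse"))
  long <- tidyr::pivot_longer(
    dplyr::select(fit_tbl, "condition_id", "model", "r2", "chi2", "rmse"),
    cols = c("r2", "chi2", "rmse"), names_to = "stat"
  )
  tidyr::pivot_wider(long, names_from = c("condition_id", "stat"),
                     values_from = "value")
}
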