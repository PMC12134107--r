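## Thin-layer model registry --------------------------------------------------
##
## Internal time unit is seconds everywhere; rate constants are therefore in
## 1/s. Conversion to 1/min is left to the presentation layer.

mr_newton <- function(t, p) exp(-p[["k"]] * t)
mr_page <- function(t, p) exp(-p[["k"]] * t^p[["n"]])
mr_modified_page <- function(t, p) exp(-(p[["k"]] * t)^p[["n"]])
mr_henderson_pabis <- function(t, p) p[["a"]] * exp(-p[["k"]] * t)
mr_logarithmic <- function(t, p) p[["a"]] * exp(-p[["k"]] * t) + p[["c"]]
mr_midilli_kucuk <- function(t, p) {
  p[["a"]] * exp(-p[["k"]] * t^p[["n"]]) + p[["b"]] * t
}
mr_wang_singh <- function(t, p) 1 + p[["a"]] * t + p[["b"]] * t^2
mr_verma <- function(t, p) {
  p[["a"]] * exp(-p[["k"]] * t) + (1 - p[["a"]]) * exp(-p[["g"]] * t)
}
mr_two_term <- function(t, p) {
  p[["a"]] * exp(-p[["k0"]] * t) + p[["b"]] * exp(-p[["k1"]] * t)
}
mr_modified_henderson_pabis <- function(t, p) {
  p[["a"]] * exp(-p[["k"]] * t) + p[["b"]] * exp(-p[["g"]] * t) +
    p[["c"]] * exp(-p[["h"]] * t)
}

## Per-parameter default fitting bounds. Rate-like constants live in
## (1e-8, 1) 1/s, shape exponents in (0.1, 5), amplitudes in (-2, 2).
## Thomson's coefficients are time-like (its form is t as a function of MR),
## so they are effectively unbounded.
RATE_PARAMS <- c("k", "g", "h", "k0", "k1")

default_param_bounds <- function(param, model = NULL) {
  if (!is.null(model) && model == "thomson") return(c(-1e8, 1e8))
  if (param %in% RATE_PARAMS) return(c(1e-8, 1))
  if (param == "n") return(c(0.1, 5))
  c(-2, 2) # amplitudes a, b, c
}

build_model_registry <- function() {
  spec <- list(
    list(name = "logarithmic", label = "Logarithmic",
         params = c("a", "k", "c"), fun = mr_logarithmic),
    list(name = "page", label = "Page", params = c("k", "n"), fun = mr_page),
    list(name = "newton", label = "Newton", params = "k", fun = mr_newton),
    list(name = "midilli_kucuk", label = "Midilli-Kucuk",
         params = c("a", "k", "n", "b"), fun = mr_midilli_kucuk),
    list(name = "wang_singh", label = "Wang-Singh",
         params = c("a", "b"), fun = mr_wang_singh),
    list(name = "verma", label = "Verma",
         params = c("a", "k", "g"), fun = mr_verma),
    list(name = "modified_page", label = "Modified Page",
         params = c("k", "n"), fun = mr_modified_page),
    list(name = "modified_henderson_pabis", label = "Modified Henderson-Pabis",
         params = c("a", "k", "b", "g", "c", "h"),
         fun = mr_modified_henderson_pabis),
    list(name = "henderson_pabis", label = "Henderson-Pabis",
         params = c("a", "k"), fun = mr_henderson_pabis),
    list(name = "two_term", label = "Two-term",
         params = c("a", "k0", "b", "k1"), fun = mr_two_term),
    list(name = "thomson", label = "Thomson", params = c("a", "b"),
         fun = NULL) # inverse form: t = a ln(MR) + b [ln(MR)]^2
  )
  tibble::tibble(
    name = purrr::map_chr(spec, "name"),
    label = purrr::map_chr(spec, "label"),
    n_params = purrr::map_int(spec, ~ length(.x$params)),
    params = purrr::map(spec, "params"),
    fun = purrr::map(spec, "fun"),
    inverse_form = purrr::map_chr(spec, "name") == "thomson",
    bounds = purrr::map(spec, function(s) {
      b <- purrr::map(s$params, default_param_bounds, model = s$name)
      names(b) <- s$params
      b
    })
  )
}

THIN_LAYER_MODELS <- build_model_registry()

#' Registry of semi-empirical thin-layer drying models
#'
#' Returns the eleven classical thin-layer models used to describe
#' moisture-ratio decay: Logarithmic, Page, Newton, Midilli-Kucuk,
#' Wang-Singh, Verma, Modified Page, Modified Henderson-Pabis,
#' Henderson-Pabis, Two-term and Thomson. All are forward forms MR(t) except
#' Thomson, which is stored in its inverse form
#' `t = a ln(MR) + b [ln(MR)]^2` and inverted for prediction.
#'
#' @return A tibble with columns `name`, `label`, `n_params`, `params`
#'   (list of parameter names), `fun` (list of MR(t; theta) functions),
#'   `inverse_form`, `bounds` (list of per-parameter `(lo, hi)` pairs).
#' @examples
#' thin_layer_models()$name
#' @export
thin_layer_models <- function() THIN_LAYER_MODELS

#' Look up one thin-layer model by name
#'
#' @param model A model name (`"newton"`, `"midilli_kucuk"`, ...) or display
#'   label (`"Midilli-Kucuk"`), or a one-row registry tibble.
#' @return A one-row tibble from [thin_layer_models()].
#' @export
get_model <- function(model) {
  if (is.data.frame(model)) {
    stopifnot(nrow(model) == 1)
    return(model)
  }
  reg <- thin_layer_models()
  hit <- reg[reg$name == model | reg$label == model, ]
  if (nrow(hit) != 1) {
    abort(sprintf("Unknown thin-layer model '%s'. Known models: %s.",
                  model, paste(reg$name, collapse = ", ")),
          class = "drykin_error_lookup")
  }
  hit
}

#' Evaluate a thin-layer model at given times
#'
#' @param model Model name or registry row (see [thin_layer_models()]).
#' @param params Named numeric vector or list with the model's parameters.
#' @param t Numeric vector of times (s), all `>= 0`.
#' @return Numeric vector of predicted moisture ratios.
#' @examples
#' evaluate_model("newton", c(k = 0.01), t = c(0, 60, 120))
#' @export
evaluate_model <- function(model, params, t) {
  model <- get_model(model)
  params <- unlist(params)
  needed <- model$params[[1]]
  if (!all(needed %in% names(params)) ||
      any(!is.finite(params[needed]))) {
    abort(sprintf("Model '%s' needs finite parameters: %s.",
                  model$name, paste(needed, collapse = ", ")),
          class = "drykin_error_parameter")
  }
  if (any(t < 0)) {
    abort("Times must be non-negative.", class = "drykin_error_domain")
  }
  if (model$inverse_form) {
    return(thomson_predict_mr(params, t))
  }
  model$fun[[1]](t, as.list(params[needed]))
}

#' Fick slab-series moisture ratio
#'
#' Analytical series solution of Fick's second law for an infinite slab of
#' half thickness `L` with uniform initial moisture, negligible surface
#' resistance and negligible equilibrium moisture:
#' `MR(t) = (8/pi^2) * sum_{n=1..N} exp(-(2n-1)^2 pi^2 Deff t / (4 L^2)) /
#' (2n-1)^2`.
#'
#' @param t Time (s), vectorised.
#' @param deff_m2s Effective moisture diffusivity (m2/s), > 0.
#' @param half_thickness_m Half slab thickness L (m), > 0.
#' @param n_terms Number of odd series terms retained (>= 1). One term gives
#'   the late-time exponential used by the slope method.
#' @return Moisture ratio in (0, 1], non-increasing in `t`.
#' @examples
#' fick_series_mr(0, 5e-10, 0.002, n_terms = 1) # 8 / pi^2
#' @export
fick_series_mr <- function(t, deff_m2s, half_thickness_m, n_terms = 200) {
  stopifnot(deff_m2s > 0, half_thickness_m > 0, n_terms >= 1)
  if (any(t < 0)) {
    abort("Times must be non-negative.", class = "drykin_error_domain")
  }
  odd <- 2 * seq_len(n_terms) - 1
  rate <- pi^2 * deff_m2s / (4 * half_thickness_m^2)
  ## outer(t, odd^2): rows = times, cols = series terms
  expo <- exp(-outer(t, odd^2) * rate)
  as.numeric(8 / pi^2 * (expo %*% (1 / odd^2)))
}

#' Invert the Thomson model to predict moisture ratio
#'
#' The Thomson model is stated in inverse form,
#' `t = a ln(MR) + b [ln(MR)]^2`. Prediction solves the quadratic in
#' `y = ln(MR)` and keeps the non-positive root; when both roots are
#' admissible the one closest to the exponential (Newton-like) trajectory
#' `y = t / a` is preferred, which is also the branch continuous in
#' `b -> 0`.
#'
#' @param params Named vector/list with `a` and `b`.
#' @param t Times (s), vectorised.
#' @return Predicted moisture ratios, with `MR(0) = 1`.
#' @export
thomson_predict_mr <- function(params, t) {
  params <- unlist(params)
  a <- params[["a"]]
  b <- params[["b"]]
  if (!is.finite(a) || !is.finite(b) || (a == 0 && b == 0)) {
    abort("Thomson requires finite parameters with a != 0 or b != 0.",
          class = "drykin_error_parameter")
  }
  y <- vapply(t, function(ti) {
    if (abs(b) < 1e-300) {
      yi <- ti / a
      if (yi > 1e-9) {
        abort("Thomson inversion has no non-positive root.",
              class = "drykin_error_domain")
      }
      return(min(yi, 0))
    }
    disc <- a^2 + 4 * b * ti
    if (disc < 0) {
      abort("Thomson inversion has no real root.",
            class = "drykin_error_domain")
    }
    roots <- c((-a + sqrt(disc)) / (2 * b), (-a - sqrt(disc)) / (2 * b))
    adm <- roots[roots <= 1e-9]
    if (length(adm) == 0) {
      abort("Thomson inversion has no non-positive root.",
            class = "drykin_error_domain")
    }
    if (length(adm) == 1) return(min(adm, 0))
    ref <- if (a != 0) ti / a else -Inf
    adm[which.min(abs(adm - ref))]
  }, numeric(1))
  exp(pmin(y, 0))
}
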