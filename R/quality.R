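## Moisture-basis conversions and physicochemical quality indices -------------

#' Dry-basis moisture content from weights
#'
#' `MC_db = (W_wet - W_dry) / W_dry`, the moisture held per unit bone-dry
#' solid.
#'
#' @param w_initial_g Wet sample weight (g).
#' @param w_dry_g Bone-dry weight (g), > 0.
#' @return Dry-basis moisture content (dimensionless), vectorised.
#' @examples
#' moisture_db(100, 40) # 1.5
#' @export
moisture_db <- function(w_initial_g, w_dry_g) {
  if (any(w_dry_g <= 0)) {
    abort("Bone-dry weight must be positive.", class = "drykin_error_domain")
  }
  (w_initial_g - w_dry_g) / w_dry_g
}

#' Convert between wet-basis and dry-basis moisture
#'
#' `wb = db / (1 + db)` and `db = wb / (1 - wb)`; the two round-trip exactly.
#'
#' @param db,wb Moisture fractions on the respective basis.
#' @return The converted moisture fraction.
#' @examples
#' wb_to_db(0.858) # ~ 6.042
#' @export
db_to_wb <- function(db) db / (1 + db)

#' @rdname db_to_wb
#' @export
wb_to_db <- function(wb) {
  if (any(wb >= 1)) {
    abort("Wet-basis moisture must be < 1.", class = "drykin_error_domain")
  }
  wb / (1 - wb)
}

#' Total CIELAB colour change
#'
#' Euclidean distance in L*a*b* space between a sample and its fresh
#' reference.
#'
#' @param l,a,b Sample CIELAB coordinates.
#' @param l0,a0,b0 Fresh-reference CIELAB coordinates.
#' @return Non-negative colour change, vectorised.
#' @examples
#' delta_e(53, 4, 10, 50, 0, 10) # 5
#' @export
delta_e <- function(l, a, b, l0, a0, b0) {
  sqrt((l - l0)^2 + (a - a0)^2 + (b - b0)^2)
}

#' Browning index from CIELAB coordinates
#'
#' Non-enzymatic browning measure via the chromaticity coordinate
#' `X = (a + 1.75 L) / (6.645 L + a - 3.012 b)` and
#' `BI = 100 (X - 0.31) / 0.17`.
#'
#' @param l,a,b Sample CIELAB coordinates.
#' @return Browning index, vectorised.
#' @examples
#' browning_index(50, 10, 20) # ~ 21.02
#' @export
browning_index <- function(l, a, b) {
  denom <- 6.645 * l + a - 3.012 * b
  if (any(abs(denom) < 1e-12)) {
    abort("Browning chromaticity denominator is zero.",
          class = "drykin_error_domain")
  }
  x <- (a + 1.75 * l) / denom
  100 * (x - 0.31) / 0.17
}

#' Shrinkage ratio from volumes
#'
#' `Sr = 1 - V_dry / V_fresh`. A dried volume above the fresh volume
#' (swelling) is allowed but triggers a warning, and the value goes
#' negative.
#'
#' @param vol_dry,vol_fresh Dried and fresh volumes (same units), > 0.
#' @return Shrinkage ratio, vectorised.
#' @examples
#' shrinkage_ratio(15, 20) # 0.25
#' @export
shrinkage_ratio <- function(vol_dry, vol_fresh) {
  if (any(vol_dry <= 0) || any(vol_fresh <= 0)) {
    abort("Volumes must be positive.", class = "drykin_error_domain")
  }
  if (any(vol_dry > vol_fresh)) {
    warn("Some dried volumes exceed fresh volumes (swelling); shrinkage ratio is negative there.")
  }
  1 - vol_dry / vol_fresh
}

#' Rehydration ratio from weights
#'
#' `RR = W_rehydrated / W_dry`.
#'
#' @param w_rehydrated,w_dry Rehydrated and dried sample weights (g), > 0.
#' @return Rehydration ratio, vectorised.
#' @examples
#' rehydration_ratio(35, 10) # 3.5
#' @export
rehydration_ratio <- function(w_rehydrated, w_dry) {
  if (any(w_rehydrated <= 0) || any(w_dry <= 0)) {
    abort("Weights must be positive.", class = "drykin_error_domain")
  }
  w_rehydrated / w_dry
}

#' Vitamin C retention
#'
#' Fraction of the fresh vitamin C concentration retained after drying,
#' `VC = V_t / V_0`. Values above 1 are flagged with a warning.
#'
#' @param vc_t Vitamin C concentration after drying (mg/g).
#' @param vc_0 Fresh vitamin C concentration (mg/g), > 0.
#' @return Retention fraction, vectorised.
#' @export
vitamin_c_retention <- function(vc_t, vc_0) {
  if (any(vc_0 <= 0)) {
    abort("Fresh vitamin C concentration must be positive.",
          class = "drykin_error_domain")
  }
  out <- vc_t / vc_0
  if (any(out > 1)) {
    warn("Some retention values exceed 1; check titre inputs.")
  }
  out
}

#' Screen water activity for microbial stability
#'
#' Flags records whose water activity reaches the stability threshold
#' (default 0.6): below it, dried produce is considered microbially stable.
#'
#' @param records Tibble with an `aw` column.
#' @param threshold Stability threshold; `aw >= threshold` is flagged.
#' @return The input with a logical `stable` column appended (empty in,
#'   empty out).
#' @export
screen_water_activity <- function(records, threshold = 0.6) {
  check_columns(records, "aw")
  dplyr::mutate(records, stable = .data$aw < threshold)
}

#' Compute all quality indices for a per-condition quality table
#'
#' Applies the colour, shrinkage, rehydration and vitamin C calculations to
#' a raw quality table (as produced by [simulate_quality_table()] or read
#' from `quality.csv`) and screens water activity.
#'
#' @param quality Tibble with columns `aw`, `l`, `a`, `b`, `l0`, `a0`, `b0`,
#'   `vol_fresh`, `vol_dry`, `w_dry`, `w_rehydrated`, `vc_t`, `vc_0`.
#' @param aw_threshold Water-activity stability threshold.
#' @return Tibble with the identifying columns of `quality` plus `aw`,
#'   `stable`, `delta_e`, `browning_index`, `shrinkage_ratio`,
#'   `rehydration_ratio`, `vitamin_c_retention`.
#' @export
compute_quality_metrics <- function(quality, aw_threshold = 0.6) {
  check_columns(quality, c("aw", "l", "a", "b", "l0", "a0", "b0",
                           "vol_fresh", "vol_dry", "w_dry", "w_rehydrated",
                           "vc_t", "vc_0"))
  id_cols <- intersect(
    c("condition_id", "temperature_c", "velocity_ms", "intensity_wm2", "rep"),
    names(quality))
  out <- dplyr::mutate(
    quality,
    delta_e = delta_e(.data$l, .data$a, .data$b, .data$l0, .data$a0,
                      .data$b0),
    browning_index = browning_index(.data$l, .data$a, .data$b),
    shrinkage_ratio = shrinkage_ratio(.data$vol_dry, .data$vol_fresh),
    rehydration_ratio = rehydration_ratio(.data$w_rehydrated, .data$w_dry),
    vitamin_c_retention = vitamin_c_retention(.data$vc_t, .data$vc_0)
  )
  out <- screen_water_activity(out, aw_threshold)
  dplyr::select(out, dplyr::all_of(id_cols), "aw", "stable", "delta_e",
                "browning_index", "shrinkage_ratio", "rehydration_ratio",
                "vitamin_c_retention")
}
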