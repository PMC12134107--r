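## Orchestration: generate -> fit -> diffusivity -> quality -> surfaces -> ML

#' Read a curves dataset from tidy CSV
#'
#' Expects the dialect written by [write_curves()]: comma-delimited, UTF-8,
#' header row, one row per time point with at least `condition_id`, `t_s`,
#' `mass_g`, `mc_db`, `mr`. Rows are re-sorted by time within each
#' condition; schema violations (missing columns, negative mass, duplicated
#' time points) raise errors naming the offending rows.
#'
#' @param path Path to a curves CSV.
#' @return A curves tibble grouped-ready by `condition_id`.
#' @export
load_curves <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  check_columns(raw, c("condition_id", "t_s", "mass_g", "mc_db", "mr"),
                arg = "curves file")
  bad_mass <- which(!is.finite(raw$mass_g) | raw$mass_g < 0)
  if (length(bad_mass) > 0) {
    abort(sprintf("Negative or missing mass at data row(s): %s.",
                  paste(head(bad_mass, 5), collapse = ", ")),
          class = "drykin_error_schema")
  }
  out <- dplyr::arrange(raw, .data$condition_id, .data$t_s)
  dup <- out |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::filter(duplicated(.data$t_s)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicated time points within condition(s): %s.",
                  paste(unique(dup$condition_id), collapse = ", ")),
          class = "drykin_error_schema")
  }
  out
}

#' Write a curves dataset as tidy CSV
#'
#' @param curves Curves tibble (see [simulate_experiment()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  check_columns(curves, c("condition_id", "t_s", "mass_g", "mc_db", "mr"))
  readr::write_csv(curves, path)
  invisible(path)
}

#' Read / write a quality table in the tidy CSV dialect
#'
#' @param path CSV path.
#' @return `load_quality()`: the quality tibble. `write_quality()`: `path`,
#'   invisibly.
#' @export
load_quality <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  check_columns(raw, c("condition_id", "aw", "l", "a", "b", "l0", "a0",
                       "b0", "vol_fresh", "vol_dry", "w_dry",
                       "w_rehydrated", "vc_t", "vc_0"),
                arg = "quality file")
  raw
}

#' @rdname load_quality
#' @param quality Quality tibble (see [simulate_quality_table()]).
#' @export
write_quality <- function(quality, path) {
  readr::write_csv(quality, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory for artifacts (`NULL` for none).
#' @return A nested configuration list: a `simulate` block mirroring
#'   [generator_params()], a `conditions` block with the factor levels,
#'   stage toggles, model list, and ANN/SOM settings.
#' @export
default_run_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    conditions = list(temperature_c = c(40, 50, 60),
                      velocity_ms = c(0.3, 0.7, 1.0),
                      intensity_wm2 = c(1500, 3500, 5500)),
    simulate = list(noise_cv = 0.01),
    quality = list(n_reps = 1),
    models = NULL, # NULL = all eleven
    fit = list(n_starts = 5, max_iter = 1000),
    deff = list(mr_window = c(0.05, 0.8)),
    ann = list(response = "aw", hidden = c(15, 15), activation = "relu",
               optimizer = "adam", learning_rate = 0.01, epochs = 300,
               n_reps = 8),
    som = list(grid_dim = c(20, 20), epochs = 10, n_clusters = 5),
    stages = list(simulate = TRUE, fit = TRUE, deff = TRUE, ea = TRUE,
                  quality = TRUE, surfaces = TRUE, ann = FALSE, som = FALSE)
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override [default_run_config()] entries.
#'
#' @param path YAML (or JSON) config file.
#' @return A merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_run_config(), user)
}

#' Run the drying-analysis pipeline end to end
#'
#' Orchestrates simulate -> thin-layer fits -> model selection ->
#' diffusivity -> activation energy -> quality metrics -> response surface
#' -> optional ANN/SOM stages as one seeded, reproducible run. All enabled
#' stages contribute a section to the returned report; if `out_dir` is set,
#' every tabular artifact is written as CSV (JSON for surfaces) as it is
#' produced, so a failing stage leaves the earlier artifacts on disk.
#'
#' @param config A configuration list (see [default_run_config()]), or `NULL`
#'   for the defaults.
#' @param config_file Optional YAML config path (overrides `config`).
#' @param seed Optional master-seed override.
#' @param out_dir Optional artifact-directory override.
#' @return A `drying_run_report` list with per-stage sections and a
#'   `provenance` block (config hash, seed, package version).
#' @export
run_pipeline <- function(config = NULL, config_file = NULL, seed = NULL,
                         out_dir = NULL) {
  cfg <- default_run_config()
  if (!is.null(config_file)) cfg <- read_run_config(config_file)
  if (!is.null(config)) cfg <- modifyList(cfg, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(cfg$out_dir) &&
      !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  save_csv <- function(obj, name) {
    if (!is.null(cfg$out_dir)) {
      readr::write_csv(obj, file.path(cfg$out_dir, paste0(name, ".csv")))
    }
  }
  save_json <- function(obj, name) {
    if (!is.null(cfg$out_dir)) {
      jsonlite::write_json(obj, file.path(cfg$out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  report <- list(provenance = list(
    config_hash = rlang::hash(cfg), seed = cfg$seed,
    package_version = as.character(utils::packageVersion("drykin")),
    timestamp = format(Sys.time(), tz = "UTC")
  ))
  class(report) <- "drying_run_report"
  on_stage <- function(name) isTRUE(cfg$stages[[name]])
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(cfg$out_dir)) {
        save_json(list(stage = name, error = conditionMessage(e)),
                  "error")
      }
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "drykin_error_pipeline", parent = e)
    })
  }

  conditions <- do.call(make_conditions_grid, cfg$conditions)
  gp <- do.call(generator_params,
                c(cfg$simulate, list(seed = cfg$seed)))
  curves <- NULL
  if (on_stage("simulate")) {
    curves <- run_stage("simulate", simulate_experiment(conditions, gp))
    save_csv(curves, "curves")
    quality <- run_stage("simulate", simulate_quality_table(
      conditions, seed = cfg$seed, n_reps = cfg$quality$n_reps))
    save_csv(quality, "quality")
    report$simulate <- list(n_conditions = nrow(conditions),
                            n_rows = nrow(curves))
    report$quality_table <- quality
  }

  if (on_stage("fit")) {
    if (is.null(curves)) {
      abort("The fit stage needs the simulate stage (or supply curves).",
            class = "drykin_error_pipeline")
    }
    fits <- run_stage("fit", fit_all_conditions(
      curves, models = cfg$models, n_starts = cfg$fit$n_starts,
      max_iter = cfg$fit$max_iter, seed = cfg$seed))
    save_csv(dplyr::select(fits, -dplyr::any_of(c("params", "fit"))),
             "fits")
    ranking <- fits |>
      dplyr::group_by(.data$condition_id) |>
      dplyr::group_modify(~ select_best(.x)) |>
      dplyr::ungroup()
    save_csv(dplyr::select(ranking, -dplyr::any_of(c("params", "fit"))),
             "ranking")
    report$fit <- list(n_fits = nrow(fits),
                       grid = fit_report_grid(fits),
                       best_by_condition = dplyr::filter(ranking,
                                                         .data$rank == 1))
    report$fits <- fits
  }

  deff_tbl <- NULL
  if (on_stage("deff")) {
    deff_tbl <- run_stage("deff", estimate_deff_all(
      curves, half_thickness_m = gp$half_thickness_m,
      mr_window = cfg$deff$mr_window))
    save_csv(deff_tbl, "deff")
    report$deff <- deff_tbl
  }
  if (on_stage("ea")) {
    if (is.null(deff_tbl)) {
      abort("The ea stage needs the deff stage.",
            class = "drykin_error_pipeline")
    }
    ea_tbl <- run_stage("ea", activation_energy_by_group(deff_tbl))
    save_csv(ea_tbl, "ea")
    report$ea <- ea_tbl
  }

  if (on_stage("quality")) {
    metrics <- run_stage("quality",
                         compute_quality_metrics(report$quality_table))
    save_csv(metrics, "quality_metrics")
    report$quality_metrics <- metrics
  }

  if (on_stage("surfaces")) {
    dt_tbl <- run_stage("surfaces", drying_time_table(curves))
    surface <- run_stage("surfaces", fit_linear_surface(dt_tbl))
    save_json(list(coefficients = as.list(surface$coefficients),
                   r2 = surface$r2, units = surface$units),
              "drying_time_surface")
    report$surfaces <- list(drying_time = surface)
  }

  if (on_stage("ann")) {
    ann_data <- run_stage("ann", simulate_quality_table(
      conditions, seed = cfg$seed + 1000, n_reps = cfg$ann$n_reps))
    ann <- run_stage("ann", train_mlp(
      ann_data, response = cfg$ann$response, hidden = cfg$ann$hidden,
      activation = cfg$ann$activation, optimizer = cfg$ann$optimizer,
      learning_rate = cfg$ann$learning_rate, epochs = cfg$ann$epochs,
      seed = cfg$seed))
    save_csv(glance(ann), "ann_metrics")
    report$ann <- ann
  }
  if (on_stage("som")) {
    som_data <- report$quality_metrics %||%
      run_stage("som", compute_quality_metrics(simulate_quality_table(
        conditions, seed = cfg$seed)))
    som <- run_stage("som", train_som(
      som_data,
      columns = c("temperature_c", "velocity_ms", "intensity_wm2", "aw",
                  "delta_e", "shrinkage_ratio", "rehydration_ratio",
                  "vitamin_c_retention"),
      grid_dim = cfg$som$grid_dim, epochs = cfg$som$epochs,
      n_clusters = cfg$som$n_clusters, seed = cfg$seed))
    save_csv(glance(som), "som_metrics")
    report$som <- som
  }
  report$config <- cfg
  report
}

#' @export
print.drying_run_report <- function(x, ...) {
  cat("<drying_run_report>\n")
  cat(sprintf("  seed %d, config %s\n", x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  if (!is.null(x$simulate)) {
    cat(sprintf("  simulate: %d conditions, %d curve rows\n",
                x$simulate$n_conditions, x$simulate$n_rows))
  }
  if (!is.null(x$fit)) {
    cat(sprintf("  fit: %d (condition, model) fits\n", x$fit$n_fits))
  }
  if (!is.null(x$deff)) {
    cat(sprintf("  deff: %d conditions, %.3g - %.3g m2/s\n",
                nrow(x$deff), min(x$deff$deff_m2s), max(x$deff$deff_m2s)))
  }
  if (!is.null(x$ea)) {
    cat(sprintf("  ea: %d (V, IR) groups, %.3g - %.3g kJ/mol\n",
                nrow(x$ea), min(x$ea$ea_kj_mol), max(x$ea$ea_kj_mol)))
  }
  if (!is.null(x$quality_metrics)) {
    cat(sprintf("  quality: %d records, all stable: %s\n",
                nrow(x$quality_metrics),
                all(x$quality_metrics$stable)))
  }
  if (!is.null(x$ann)) {
    cat(sprintf("  ann: test R2 = %.3f for %s\n", x$ann$metrics$r2,
                x$ann$response))
  }
  if (!is.null(x$som)) {
    cat(sprintf("  som: %d units, %d clusters\n", prod(x$som$grid_dim),
                x$som$n_clusters))
  }
  invisible(x)
}
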