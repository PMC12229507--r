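# End-to-end orchestration: simulate -> preprocess -> stats -> select ->
# train -> evaluate, with a reproducible output manifest.

#' Pipeline configuration
#'
#' Collects the per-stage configurations of the end-to-end run. All
#' randomness (calibration, dataset generation, balancing, splits, folds)
#' derives from the single `seed`.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for CSVs and the JSON manifest.
#' @param synth [synth_config()] for the generator.
#' @param calibrate Whether to resolve band deltas with
#'   [calibrate_band_deltas()] before generating.
#' @param calibration_reps Replicates per calibration round.
#' @param preprocess [preprocess_config()].
#' @param stats List: `multiplier` (double-SD rule), `half_window` (cm^-1),
#'   optional `panel_path` for a custom band panel CSV.
#' @param classify List: `kernels`, `feature_modes`, `train_frac`, `folds`,
#'   `cost`.
#' @param profiles List: `amp_jitter`, `background_shift`, optional
#'   `n_per_line`.
#' @return A list of class `fgrs_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = "fgrs-run",
                            synth = synth_config(seed = seed),
                            calibrate = TRUE,
                            calibration_reps = c(16, 32),
                            preprocess = preprocess_config(),
                            stats = list(multiplier = 2, half_window = 4,
                                         panel_path = NULL),
                            classify = list(kernels = c("coarse", "medium"),
                                            feature_modes = c("all", "selected"),
                                            train_frac = 0.8, folds = 5,
                                            cost = 1),
                            profiles = list(amp_jitter = 0.05,
                                            background_shift = 0.1,
                                            n_per_line = NULL)) {
  cfg <- list(seed = seed, out_dir = out_dir, synth = synth,
              calibrate = calibrate, calibration_reps = calibration_reps,
              preprocess = preprocess, stats = stats, classify = classify,
              profiles = profiles)
  class(cfg) <- "fgrs_pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration before execution
#'
#' @param cfg A [pipeline_config()] (or plain list in its shape).
#' @return The validated config, invisibly; malformed configs abort with a
#'   condition of class `fgrs_config_error`.
#' @export
validate_pipeline_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "fgrs_config_error")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) fail("`seed` must be one number")
  if (!inherits(cfg$synth, "fgrs_synth_config")) fail("`synth` must be a synth_config()")
  if (!inherits(cfg$preprocess, "fgrs_preprocess_config")) {
    fail("`preprocess` must be a preprocess_config()")
  }
  if (!is.null(cfg$stats$panel_path) && !file.exists(cfg$stats$panel_path)) {
    fail(sprintf("band panel file not found: %s", cfg$stats$panel_path))
  }
  if (!all(cfg$classify$kernels %in% c("coarse", "medium"))) {
    fail("`classify$kernels` must be drawn from coarse, medium")
  }
  if (!all(cfg$classify$feature_modes %in% c("all", "selected"))) {
    fail("`classify$feature_modes` must be drawn from all, selected")
  }
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Recognized top-level keys: `seed`, `out_dir`, `calibrate`,
#' `calibration_reps`, and sections `synth` (`n_per_class`, `noise_sd`,
#' `cosmic_rate`, `cosmic_amp_factor`), `preprocess` (any
#' [preprocess_config()] argument), `stats`, `classify`, `profiles`.
#' Unspecified values keep their defaults.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "fgrs_config_error")
  }
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  seed <- raw$seed %||% 1
  synth_args <- raw$synth %||% list()
  synth_args$seed <- seed
  pre <- do.call(preprocess_config, raw$preprocess %||% list())
  pipeline_config(
    seed = seed,
    out_dir = raw$out_dir %||% "fgrs-run",
    synth = do.call(synth_config, synth_args),
    calibrate = raw$calibrate %||% TRUE,
    calibration_reps = raw$calibration_reps %||% c(16, 32),
    preprocess = pre,
    stats = modifyList(list(multiplier = 2, half_window = 4,
                            panel_path = NULL), raw$stats %||% list()),
    classify = modifyList(list(kernels = c("coarse", "medium"),
                               feature_modes = c("all", "selected"),
                               train_frac = 0.8, folds = 5, cost = 1),
                          raw$classify %||% list()),
    profiles = modifyList(list(amp_jitter = 0.05, background_shift = 0.1,
                               n_per_line = NULL), raw$profiles %||% list())
  )
}

#' Run the full pipeline
#'
#' Executes calibrate (optional), simulate, preprocess, band statistics,
#' double-SD channel selection, and the SVM experiment grid, writing
#' `band_stats.csv`, `feature_mask.csv`, `experiment_table.csv`, per-cell
#' ROC curves and a JSON run manifest into `out_dir`. Re-running with the
#' same config and seed reproduces every CSV byte for byte (the manifest's
#' timing block is the one run-dependent output).
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (defaults to `cfg$out_dir`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the band stats, mask, experiment table and
#'   manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = cfg$out_dir,
                         quiet = FALSE) {
  validate_pipeline_config(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - start, 3)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- if (is.null(cfg$stats$panel_path)) default_band_panel() else
    load_band_panel(cfg$stats$panel_path)
  seeds <- .child_seeds(cfg$seed, 3)

  synth <- cfg$synth
  if (isTRUE(cfg$calibrate)) {
    s <- proc.time()[["elapsed"]]
    synth <- calibrate_band_deltas(synth, n_reps = cfg$calibration_reps,
                                   seed = seeds[[1]], panel = panel,
                                   preprocess = cfg$preprocess,
                                   half_window = cfg$stats$half_window)
    tick("calibrate", s)
    say("calibrated %d band contrasts", sum(synth$bands$target_d > 0))
  }

  s <- proc.time()[["elapsed"]]
  sets <- make_cell_line_profiles(synth,
                                  amp_jitter = cfg$profiles$amp_jitter,
                                  background_shift = cfg$profiles$background_shift,
                                  n_per_line = cfg$profiles$n_per_line,
                                  seed = seeds[[2]])
  tick("simulate", s)
  say("simulated %d cell-line sets (%d spectra each)", length(sets),
      length(unique(sets[[1]]$sample_id)))

  s <- proc.time()[["elapsed"]]
  pp <- lapply(sets, preprocess_spectra, config = cfg$preprocess)
  tick("preprocess", s)
  n_spikes <- sum(vapply(pp, function(x) sum(attr(x, "log")$n_cosmic_removed),
                         numeric(1)))
  say("preprocessed %d spectra, removed %d cosmic rays",
      sum(vapply(pp, function(x) length(unique(x$sample_id)), numeric(1))),
      n_spikes)

  training <- as_spectra(dplyr::bind_rows(pp$transfected, pp$control))
  positive <- synth$labels[["high"]]

  s <- proc.time()[["elapsed"]]
  stats_tbl <- band_stats_table(training,
                                labels = unname(synth$labels[c("high", "low")]),
                                panel = panel,
                                half_window = cfg$stats$half_window)
  gs <- group_summaries(training)
  mask <- double_sd_mask(gs[[synth$labels[["high"]]]],
                         gs[[synth$labels[["low"]]]],
                         multiplier = cfg$stats$multiplier)
  tick("stats", s)
  say("double-SD rule selected %d of %d channels",
      attr(mask, "n_selected"), nrow(mask))

  s <- proc.time()[["elapsed"]]
  testing <- list(
    testing1 = as_spectra(dplyr::bind_rows(pp$transfected, pp$wildtype)),
    testing2 = as_spectra(dplyr::bind_rows(pp$U87MG, pp$T98G, pp$Ln229,
                                           pp$Ln18))
  )
  experiment <- run_experiment(
    training, testing = testing, mask = mask, positive = positive,
    kernels = cfg$classify$kernels,
    feature_modes = cfg$classify$feature_modes,
    train_frac = cfg$classify$train_frac, folds = cfg$classify$folds,
    cost = cfg$classify$cost, seed = seeds[[3]]
  )
  tick("classify", s)

  paths <- list(
    band_stats = file.path(out_dir, "band_stats.csv"),
    feature_mask = file.path(out_dir, "feature_mask.csv"),
    experiment = file.path(out_dir, "experiment_table.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(as_tibble(stats_tbl), paths$band_stats, progress = FALSE)
  readr::write_csv(tibble(wavenumber = mask$wavenumber,
                          selected = as.integer(mask$selected)),
                   paths$feature_mask, progress = FALSE)
  readr::write_csv(as_tibble(experiment), paths$experiment, progress = FALSE)
  rocs <- attr(experiment, "roc")
  for (nm in names(rocs)) {
    fn <- file.path(out_dir, paste0("roc_", gsub("/", "_", nm), ".csv"))
    readr::write_csv(rocs[[nm]], fn, progress = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fgrs")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    calibrated = isTRUE(cfg$calibrate),
    n_sets = length(sets),
    n_spectra = sum(vapply(pp, function(x) length(unique(x$sample_id)),
                           numeric(1))),
    n_cosmic_removed = n_spikes,
    mask_n_selected = attr(mask, "n_selected"),
    mask_threshold = attr(mask, "threshold_value"),
    mask_hash = rlang::hash(mask$selected),
    timings_s = timings,
    total_s = round(proc.time()[["elapsed"]] - t0, 3)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote outputs to %s (%.1f s)", out_dir, manifest$total_s)
  invisible(list(band_stats = stats_tbl, mask = mask,
                 experiment = experiment, manifest = manifest,
                 paths = paths))
}
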