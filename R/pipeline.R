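# End-to-end pipeline orchestration: the four stages behind the command-line
# entry point (simulate -> extract -> optimize -> report). Every stage logs
# its seeds and row accounting, reads/writes plain CSV + JSON only, and
# derives its own seed from the master seed so stages can be re-run
# independently and byte-identically.

stage_log <- function(level, fmt, ...) {
  if (identical(getOption("mmgtorque.quiet", FALSE), TRUE)) return(invisible())
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Simulate a batch of recordings to CSV
#'
#' Writes `n_trials` recordings (`recording_<k>.csv` plus metadata sidecars)
#' and a `manifest.json` listing files, per-trial derived seeds and per-trial
#' stimulation levels. Trials are simulated at graded torque levels spanning
#' `level_range` (evenly spaced), emulating a study that pools recordings
#' from different stimulation intensities and joint configurations — which
#' is what makes the pooled feature table span the full torque scale.
#'
#' @param cfg A [synth_config()]; its `n_trials` and `seed` drive the batch.
#' @param out_dir Output directory (created if needed).
#' @param level_range Per-trial plateau torque as a fraction of
#'   `cfg$torque_max`; a single trial uses the upper end.
#' @return The manifest as a list, invisibly.
#' @export
pipeline_simulate <- function(cfg, out_dir, level_range = c(1 / 3, 1)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  levels <- if (cfg$n_trials == 1) level_range[2] else {
    seq(level_range[1], level_range[2], length.out = cfg$n_trials)
  }
  files <- character(cfg$n_trials)
  seeds <- integer(cfg$n_trials)
  for (k in seq_len(cfg$n_trials)) {
    rec <- simulate_recording(cfg, trial = k, level = levels[k])
    rec$meta$level <- levels[k]
    files[k] <- file.path(out_dir, sprintf("recording_%02d.csv", k))
    seeds[k] <- derive_seed(cfg$seed, k)
    write_recording(rec, files[k])
  }
  manifest <- list(
    master_seed = cfg$seed, trial_seeds = seeds, files = basename(files),
    levels = levels, fs = cfg$fs, trial_s = cfg$trial_s
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log("INFO", "simulate: wrote %d recordings to %s", cfg$n_trials, out_dir)
  invisible(manifest)
}

#' Extract, normalize and censor features from recording CSVs
#'
#' For each recording: band-pass the MMG (5-100 Hz), low-pass the torque
#' (5 Hz), trim the 6 s head/tail transients, window and extract the 12
#' features + torque RMS target. The pooled table is then Z-scored with
#' |z| > `censor_threshold` row censoring and min-max scaled to [0, 1].
#' Row-count accounting (raw windows, removed, retained) is logged.
#'
#' @param recording_paths Character vector of recording CSV paths.
#' @param out_csv Output feature-table CSV path (`NULL` to skip writing).
#' @param wspec A [window_spec()].
#' @param head_s,tail_s Transient trim in seconds.
#' @param censor_threshold Z-score censoring threshold.
#' @return A list with `table` (the final tibble), `states` (the two
#'   `norm_state`s), and `accounting` (raw/removed/retained counts).
#' @export
pipeline_extract <- function(recording_paths, out_csv = NULL,
                             wspec = window_spec(), head_s = 6, tail_s = 6,
                             censor_threshold = 3) {
  tabs <- purrr::map(recording_paths, function(p) {
    rec <- read_recording(p)
    rec$mmg <- bandpass_mmg(rec$mmg, rec$fs)
    rec$torque <- lowpass_torque(rec$torque, rec$fs)
    rec <- trim_transients(rec, head_s, tail_s)
    extract_feature_table(rec, wspec)
  })
  raw <- dplyr::bind_rows(tabs)
  z <- zscore_censor(raw, censor_threshold)
  mm <- minmax_scale(z$table)
  accounting <- list(raw_windows = nrow(raw), removed = z$removed,
                     retained = nrow(mm$table))
  stage_log("INFO", "extract: %d windows, %d censored (|z| > %g), %d retained",
            accounting$raw_windows, accounting$removed, censor_threshold,
            accounting$retained)
  if (!is.null(out_csv)) {
    utils::write.csv(mm$table, out_csv, row.names = FALSE)
    jsonlite::write_json(
      list(
        zscore = list(columns = z$state$columns,
                      center = unname(z$state$center),
                      scale = unname(z$state$scale)),
        minmax = list(columns = mm$state$columns,
                      min = unname(mm$state$min),
                      max = unname(mm$state$max)),
        accounting = accounting
      ),
      paste0(sub("\\.csv$", "", out_csv), "_normstate.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(table = mm$table, states = list(zscore = z$state, minmax = mm$state),
       accounting = accounting)
}

#' Run an optimization (or baseline) stage on a feature table
#'
#' @param table Feature table, or a path to one written by
#'   [pipeline_extract()].
#' @param algorithm `"GLEO"` or `"EO"`.
#' @param mode `"FS_HT"`, `"FS"`, or `"HT"`.
#' @param baseline `"none"` (run the metaheuristic), `"default"` (untuned
#'   forest), or `"grid"` (grid search).
#' @param out_prefix If non-`NULL`, writes `<prefix>_result.json` and
#'   `<prefix>_trace.csv`.
#' @param ... Passed on to [run_optimizer()] / [grid_search_ht()] /
#'   [baseline_rfr()] (e.g. `n_pop`, `max_iter`, `seed`, `split`).
#' @return A `gleo_run`.
#' @export
pipeline_optimize <- function(table, algorithm = "GLEO", mode = "FS_HT",
                              baseline = c("none", "default", "grid"),
                              out_prefix = NULL, ...) {
  baseline <- match.arg(baseline)
  if (is.character(table)) table <- tibble::as_tibble(utils::read.csv(table))
  run <- switch(
    baseline,
    none = run_optimizer(table, algorithm = algorithm, mode = mode, ...),
    default = baseline_rfr(table, ...),
    grid = grid_search_ht(table, ...)
  )
  stage_log("INFO", "optimize: %s-%s test RMSE %.4f R2 %.4f",
            run$algorithm, run$mode, run$test_metrics$rmse,
            run$test_metrics$r2)
  if (!is.null(out_prefix)) {
    g <- glance(run)
    jsonlite::write_json(
      list(
        algorithm = run$algorithm, mode = run$mode, seed = run$seed,
        selected_features = run$best_mask,
        config = list(
          n_trees = run$best_config$n_trees,
          m_trees = run$best_config$m_trees,
          min_leaf_size = run$best_config$min_leaf_size,
          n_splits = if (is.finite(run$best_config$n_splits))
            run$best_config$n_splits else "Inf"
        ),
        metrics = list(rmse = g$test_rmse, r2 = g$test_r2,
                       slope = g$test_slope)
      ),
      paste0(out_prefix, "_result.json"), auto_unbox = TRUE, digits = NA
    )
    utils::write.csv(run$trace, paste0(out_prefix, "_trace.csv"),
                     row.names = FALSE)
  }
  run
}

#' Comparison report over a set of runs
#'
#' One row per run with R2 / RMSE / slope on the test subset; the best-R2
#' row is flagged.
#'
#' @param ... `gleo_run` objects (or a single list of them).
#' @param out_csv Optional CSV output path.
#' @return A tibble with columns `model`, `r2`, `rmse`, `slope`, `best`.
#' @export
pipeline_report <- function(..., out_csv = NULL) {
  runs <- list(...)
  if (length(runs) == 1 && !inherits(runs[[1]], "gleo_run")) runs <- runs[[1]]
  tab <- purrr::map_dfr(runs, function(r) {
    label <- if (r$algorithm == "NONE") "RFR"
      else paste0(r$algorithm, "-RFR-", gsub("_", "-", r$mode))
    tibble::tibble(model = label, r2 = r$test_metrics$r2,
                   rmse = r$test_metrics$rmse, slope = r$test_metrics$slope)
  })
  tab$best <- seq_len(nrow(tab)) == which.max(tab$r2)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
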