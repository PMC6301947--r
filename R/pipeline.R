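#' Simulate a scenario and archive it to disk
#'
#' Writes `tracks.csv` (canonical schema), `ground_truth.csv` (per-cell
#' phenotype and effective burst parameters) and `config.json` (the exact
#' configuration used, so a run can be reproduced bit-identically) to
#' `out_dir`.
#'
#' @param scenario A preset label (see [preset()]) or a full
#'   [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; overrides the config's seed when supplied.
#' @param overrides Named list of `sim_config` fields to override (e.g.
#'   `list(n_cells = 10)`).
#' @return Invisibly, the result of [simulate_population()].
#' @export
run_simulate <- function(scenario, out_dir, seed = NULL,
                         overrides = list()) {
  config <- if (inherits(scenario, "sim_config")) scenario else preset(scenario)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  for (nm in names(overrides)) {
    if (!nm %in% names(config)) stop("unknown config field: ", nm, call. = FALSE)
    config[[nm]] <- overrides[[nm]]
  }
  config <- sim_config(n_cells = config$n_cells,
                       fraction_fast = config$fraction_fast,
                       slow_params = config$slow_params,
                       fast_params = config$fast_params,
                       drug_effect = config$drug_effect,
                       scenario = config$scenario,
                       n_frames = config$n_frames,
                       frame_interval_min = config$frame_interval_min,
                       seed = config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_population(config)
  write_tracks(sim$tracks, file.path(out_dir, "tracks.csv"))
  utils::write.csv(sim$truth$cells, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- config
  cfg$slow_params <- unclass(cfg$slow_params)
  cfg$fast_params <- unclass(cfg$fast_params)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Analyze one population of tracks end to end
#'
#' Runs the full single-population pipeline — per-cell kinematic metrics,
#' movement-peak detection, burst metrics, the speed topography, the
#' log-normal fit of per-cell mean speeds, the fast-subpopulation call,
#' the displacement-vs-variability summary and the
#' variability-vs-effective-speed correlation — and writes
#' `cell_metrics.csv`, `peaks.csv`, `topography.csv` (+
#' `topography_rows.json` sidecar with row order and sd values),
#' `population_summary.json` and `analysis_config.json` to `out_dir`.
#'
#' @param tracks A [track_set()] or a path to a canonical tracks CSV.
#' @param out_dir Output directory.
#' @param pixel_size_um,frame_interval_min Used only when `tracks` is a
#'   path.
#' @param peak_epsilon,high_speed_threshold Burst thresholds (um/hr).
#' @param fast_quantile Quantile defining the fast subpopulation.
#' @return Invisibly, a list with the per-cell `table`, `peaks`,
#'   `topography`, `lognormal` fit (or NULL), `fast`, `summary` and
#'   `correlation`.
#' @export
run_analyze <- function(tracks, out_dir, pixel_size_um = 1,
                        frame_interval_min = 11, peak_epsilon = 0,
                        high_speed_threshold = 20, fast_quantile = 0.95) {
  if (is.character(tracks)) {
    tracks <- read_tracks(tracks, dialect = "csv",
                          pixel_size_um = pixel_size_um,
                          frame_interval_min = frame_interval_min)
  }
  .assert_track_set(tracks)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tab <- condition_table(tracks, high_speed_threshold = high_speed_threshold,
                         peak_epsilon = peak_epsilon)
  ser <- speed_series(tracks)
  peaks <- detect_peaks(ser, threshold = peak_epsilon)
  peaks$is_high_speed <- peaks$max_speed > high_speed_threshold
  topo <- topography(tracks)
  fit <- tryCatch(suppressMessages(fit_lognormal(tab$mean_speed)),
                  error = function(e) NULL)
  fast <- tryCatch(fast_subpopulation(tab, quantile = fast_quantile),
                   error = function(e) NULL)
  summ <- scatter_summary(tab)
  corr <- tryCatch(spearman_cor(tab$sd_instantaneous_speed,
                                tab$mean_effective_speed),
                   error = function(e) NULL)

  lab <- track_label(tracks)
  utils::write.csv(cbind(tab, tumor_id = lab$tumor_id,
                         amplification = lab$amplification,
                         treatment = lab$treatment),
                   file.path(out_dir, "cell_metrics.csv"), row.names = FALSE)
  utils::write.csv(peaks, file.path(out_dir, "peaks.csv"), row.names = FALSE)
  topo_df <- as.data.frame(topo$speed)
  names(topo_df) <- sprintf("t_%.3f_hr", topo$time_hr)
  utils::write.csv(cbind(cell_id = topo$cell_id, topo_df),
                   file.path(out_dir, "topography.csv"), row.names = FALSE)
  jsonlite::write_json(list(row_order = topo$cell_id, sd = topo$sd),
                       file.path(out_dir, "topography_rows.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    label = unclass(lab),
    n_cells = nrow(tab),
    lognormal_fit = if (is.null(fit))
      NULL else fit[c("mu", "sigma", "r_squared", "n_bins", "n_cells")],
    fast_subpopulation = fast,
    centroid = as.list(summ$centroid),
    centroid_sd = as.list(summ$centroid_sd),
    quadrant_counts = as.list(summ$quadrant_counts),
    sd_vs_effective_speed = if (is.null(corr)) NULL else unclass(corr)),
    file.path(out_dir, "population_summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(peak_epsilon = peak_epsilon,
                            high_speed_threshold = high_speed_threshold,
                            fast_quantile = fast_quantile,
                            frame_interval_min = frame_interval(tracks)),
                       file.path(out_dir, "analysis_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table = tab, peaks = peaks, topography = topo,
                 lognormal = fit, fast = fast, summary = summ,
                 correlation = corr))
}

#' Compare a control and a drug-treated population and archive the report
#'
#' Runs [compare_conditions()] and writes `comparison.json` (all metric
#' tests, Levene results, centroids and quadrant counts) plus
#' `pooled_cells.csv` (both conditions' per-cell tables with condition
#' labels) to `out_dir`.
#'
#' @param control,drug [track_set()]s or paths to canonical tracks CSVs.
#' @param out_dir Output directory.
#' @param frame_interval_min Used only for path inputs.
#' @param ... Passed to [compare_conditions()].
#' @return Invisibly, the [compare_conditions()] result.
#' @export
run_compare <- function(control, drug, out_dir, frame_interval_min = 11,
                        ...) {
  if (is.character(control)) {
    control <- read_tracks(control, dialect = "csv",
                           frame_interval_min = frame_interval_min)
  }
  if (is.character(drug)) {
    drug <- read_tracks(drug, dialect = "csv",
                        frame_interval_min = frame_interval_min)
  }
  cmp <- compare_conditions(control, drug, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tc <- cbind(condition_table(control,
                              cmp$settings$high_speed_threshold,
                              cmp$settings$peak_epsilon),
              treatment = "control")
  td <- cbind(condition_table(drug,
                              cmp$settings$high_speed_threshold,
                              cmp$settings$peak_epsilon),
              treatment = "drug")
  utils::write.csv(rbind(tc, td), file.path(out_dir, "pooled_cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    n_control = cmp$n_control, n_drug = cmp$n_drug, alpha = cmp$alpha,
    settings = cmp$settings,
    tests = cmp$tests, levene = cmp$levene,
    control_centroid = as.list(cmp$control_summary$centroid),
    drug_centroid = as.list(cmp$drug_summary$centroid),
    control_quadrants = as.list(cmp$control_summary$quadrant_counts),
    drug_quadrants = as.list(cmp$drug_summary$quadrant_counts)),
    file.path(out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(cmp)
}
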