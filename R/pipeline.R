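#' Analysis configuration
#'
#' Central configuration of an end-to-end run. All values have defaults
#' mirroring the analysis conditions: ON threshold 350 a.u., 2.5-min
#' frames over 60 min, stage boundaries at equal sextiles, bootstrap of
#' 10,000 resamples of size 31, LOWESS span 0.3.
#'
#' @param on_threshold ON/OFF threshold (a.u.), > 0.
#' @param frame_interval imaging interval (min), > 0.
#' @param duration imaging window (min), > 0.
#' @param threshold_sweep numeric grid for the complete-burst threshold
#'   sweep.
#' @param robustness_thresholds thresholds over which stage rankings are
#'   re-checked.
#' @param stage_boundaries five increasing cut points in (0, 1).
#' @param marker_cofactor asinh cofactor for the marker transform.
#' @param bootstrap_n,bootstrap_resamples bootstrap subsample size and
#'   resample count.
#' @param classifier_span LOWESS span of the behaviour classifier.
#' @param classifier_score `"deviation"` (basal amplitude deviation score)
#'   or `"fano"` (Fano-factor based alternative).
#' @param n_cells_per_stage synthetic cells generated per stage.
#' @param marker_noise_cv lognormal CV of simulated marker noise.
#' @param seed master seed.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(on_threshold = 350, frame_interval = 2.5,
                            duration = 60,
                            threshold_sweep = seq(100, 900, by = 25),
                            robustness_thresholds = seq(250, 450, by = 50),
                            stage_boundaries = seq(1 / 6, 5 / 6, by = 1 / 6),
                            marker_cofactor = 150,
                            bootstrap_n = 31, bootstrap_resamples = 10000,
                            classifier_span = 0.3,
                            classifier_score = c("deviation", "fano"),
                            n_cells_per_stage = 100,
                            marker_noise_cv = 0.2,
                            seed = 1) {
  classifier_score <- match.arg(classifier_score)
  cfg <- structure(as.list(environment()), class = "analysis_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  cfg_err <- function(msg) {
    e <- simpleError(paste0("configuration error: ", msg))
    class(e) <- c("configuration_error", class(e))
    stop(e)
  }
  if (!is.numeric(cfg$on_threshold) || cfg$on_threshold <= 0)
    cfg_err("on_threshold must be positive")
  if (cfg$frame_interval <= 0 || cfg$duration <= 0 ||
      cfg$duration < cfg$frame_interval)
    cfg_err("duration and frame_interval must be positive with duration >= frame_interval")
  if (any(diff(cfg$stage_boundaries) <= 0) ||
      any(cfg$stage_boundaries <= 0) || any(cfg$stage_boundaries >= 1))
    cfg_err("stage_boundaries must be strictly increasing within (0, 1)")
  if (cfg$bootstrap_n < 1 || cfg$bootstrap_resamples < 1)
    cfg_err("bootstrap settings must be positive")
  if (cfg$classifier_span <= 0 || cfg$classifier_span > 1)
    cfg_err("classifier_span must be in (0, 1]")
  if (cfg$n_cells_per_stage < 0) cfg_err("n_cells_per_stage must be >= 0")
  invisible(cfg)
}

#' Read / write an analysis configuration as YAML
#'
#' Round-trip stable: `read_config(write_config(cfg, path))` equals
#' `cfg`.
#'
#' @param cfg an [analysis_config()].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

#' Read / write spot-intensity traces as CSV
#'
#' The interchange format between stages: columns `cell_id`, `time_min`,
#' `intensity_au`, one row per sample.
#'
#' @param traces list of [intensity_trace()] objects.
#' @param path file path.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   returns a named list of [intensity_trace()] objects in file order.
#' @export
write_traces_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, time_min = tr$times,
               intensity_au = tr$intensities, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "time_min", "intensity_au") %in% names(df)))
  ids <- unique(df$cell_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$cell_id == id, ]
    intensity_trace(id, sub$time_min, sub$intensity_au)
  })
  names(out) <- ids
  out
}

## Stable md5 of an R object via its serialisation.
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Stage-ranking robustness across ON thresholds
#'
#' Recomputes each stage's median ON fraction at every threshold in the
#' grid and reports whether the stage ranking is identical across the
#' whole grid (the conclusion-stability check behind using a single ON
#' threshold).
#'
#' @param traces list of [intensity_trace()] objects.
#' @param stage factor of stage labels, one per trace.
#' @param thresholds numeric threshold grid.
#' @return List: `medians` (thresholds x stages matrix), `invariant`
#'   (logical), `rank_table`.
#' @export
stage_rank_robustness <- function(traces, stage, thresholds) {
  stopifnot(length(traces) == length(stage))
  med <- t(vapply(thresholds, function(th) {
    onf <- vapply(traces, function(tr)
      summarize_bursts(tr, th)$summary$on_fraction, numeric(1))
    tapply(onf, stage, stats::median)
  }, numeric(length(levels(factor(stage))))))
  rownames(med) <- thresholds
  ranks <- t(apply(med, 1, rank, ties.method = "first"))
  invariant <- all(apply(ranks, 2, function(cl) length(unique(cl)) == 1))
  list(medians = med, invariant = invariant, rank_table = ranks)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a population under the default stage profiles, stages cells
#' from their markers, computes burst metrics at the configured ON
#' threshold, the threshold sweep, per-stage variability statistics with
#' bootstrap confidence intervals, Fano-versus-mean regressions with
#' slope ratios, Mann-Whitney stage comparisons, the behaviour
#' classification and its per-stage proportions, and the stage-ranking
#' robustness check. All tables are written as CSV under `outdir`
#' together with a JSON run manifest.
#'
#' @param config an [analysis_config()].
#' @param outdir output directory (created if missing); `NULL` skips
#'   writing.
#' @param cells optional pre-simulated population (list of
#'   `synthetic_cell`); by default one is simulated from the config.
#' @return Result bundle (list) with the tables described above and the
#'   manifest, invisibly the same object that was written.
#' @export
run_pipeline <- function(config = analysis_config(), outdir = NULL,
                         cells = NULL) {
  validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  warnings_log <- character(0)

  if (is.null(cells)) {
    cells <- simulate_population(default_stage_profiles(),
                                 config$n_cells_per_stage,
                                 duration = config$duration,
                                 frame_interval = config$frame_interval,
                                 marker_noise_cv = config$marker_noise_cv,
                                 seed = config$seed)
  }
  if (length(cells) == 0) {
    e <- simpleError("configuration error: no cells to analyse")
    class(e) <- c("configuration_error", class(e))
    stop(e)
  }
  truth <- population_table(cells)
  traces <- lapply(cells, `[[`, "trace")

  # staging from markers
  staged <- stage_cells(truth[, c("cell_id", "cd71", "ter119")],
                        cofactor = config$marker_cofactor,
                        boundaries = config$stage_boundaries)

  # burst metrics
  bm <- summarize_bursts_all(traces, threshold = config$on_threshold)
  summary <- merge(bm$summary,
                   staged[, c("cell_id", "position", "stage")],
                   by = "cell_id", sort = FALSE)
  summary <- merge(summary,
                   truth[, c("cell_id", "true_regime", "true_position")],
                   by = "cell_id", sort = FALSE)
  fano <- vapply(traces, function(tr) fano_factor(tr)$fano, numeric(1))
  names(fano) <- vapply(traces, function(tr) as.character(tr$cell_id),
                        character(1))
  summary$fano <- fano[summary$cell_id]
  n_excluded_fano <- sum(!is.finite(summary$fano))
  if (n_excluded_fano > 0)
    warnings_log <- c(warnings_log,
                      sprintf("%d cells with non-positive mean excluded from Fano analyses",
                              n_excluded_fano))

  sweep <- threshold_sweep(traces, config$threshold_sweep)

  # per-stage statistics
  stages <- levels(summary$stage)
  stage_stats <- do.call(rbind, lapply(seq_along(stages), function(i) {
    s <- stages[i]
    rows <- summary[summary$stage == s, ]
    if (nrow(rows) == 0)
      return(data.frame(stage = s, n = 0, median_mean_intensity = NA,
                        ci_low = NA, ci_high = NA,
                        median_on_fraction = NA, fano_slope = NA,
                        slope_ratio = NA))
    ci <- bootstrap_median_ci(rows$mean_intensity,
                              subsample_n = config$bootstrap_n,
                              n_resamples = config$bootstrap_resamples,
                              seed = config$seed + i)
    slope <- tryCatch(
      fano_mean_regression(rows$mean_intensity, rows$fano)$slope,
      error = function(e) NA_real_)
    data.frame(stage = s, n = nrow(rows),
               median_mean_intensity = ci$point_median,
               ci_low = ci$ci_low, ci_high = ci$ci_high,
               median_on_fraction = stats::median(rows$on_fraction),
               fano_slope = slope, slope_ratio = NA_real_)
  }))
  ok <- is.finite(summary$fano)
  pooled_slope <- fano_mean_regression(summary$mean_intensity[ok],
                                       summary$fano[ok])$slope
  stage_stats$slope_ratio <- relative_variability(stage_stats$fano_slope,
                                                  pooled_slope)
  r2_onfrac <- explained_variance(summary$on_fraction,
                                  summary$mean_intensity)

  groups_mi <- split(summary$mean_intensity, summary$stage)
  groups_of <- split(summary$on_fraction, summary$stage)
  keep <- vapply(groups_mi, length, integer(1)) >= 3
  tests <- rbind(
    cbind(metric = "mean_intensity", compare_stages(groups_mi[keep])),
    cbind(metric = "on_fraction", compare_stages(groups_of[keep])))

  # behaviour classification
  cls <- classify_population(summary, span = config$classifier_span,
                             window = config$duration)
  cls_cells <- merge(cls$cells,
                     summary[, c("cell_id", "stage", "true_regime")],
                     by = "cell_id", sort = FALSE)
  props <- stage_proportions(cls_cells$stage, cls_cells$final_class)

  robustness <- stage_rank_robustness(traces, summary$stage,
                                      config$robustness_thresholds)

  manifest <- list(
    config_hash = object_digest(unclass(config)),
    package_version = as.character(utils::packageVersion("burststage")),
    n_cells = nrow(summary),
    cells_per_stage = as.list(table(summary$stage)),
    pooled_fano_slope = pooled_slope,
    r_squared_on_fraction = r2_onfrac,
    inflection_duration = cls$inflection$inflection_duration,
    inflection_fraction = cls$inflection$inflection_fraction,
    deviation_threshold = cls$threshold,
    rank_order_invariant = robustness$invariant,
    n_excluded_fano = n_excluded_fano,
    warnings = warnings_log,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))

  bundle <- list(truth = truth, traces = traces, staged = staged,
                 summary = summary, bursts = bm$bursts, sweep = sweep,
                 stage_stats = stage_stats, tests = tests,
                 classification = cls_cells, class_details = cls,
                 proportions = props, robustness = robustness,
                 manifest = manifest, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
    wr(trace_table(cells), "traces.csv")
    wr(truth, "ground_truth.csv")
    wr(staged, "staged_cells.csv")
    wr(summary, "burst_summary.csv")
    wr(bm$bursts, "bursts.csv")
    wr(sweep$table, "threshold_sweep.csv")
    wr(stage_stats, "stage_stats.csv")
    wr(tests, "pairwise_tests.csv")
    wr(cls_cells, "classification.csv")
    wr(as.data.frame.matrix(props$proportions), "stage_proportions.csv")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}

#' Boxplot statistics with 9th/91st-percentile whiskers
#'
#' @param values numeric vector.
#' @return data.frame: `lower` (9th percentile), `q1`, `median`, `q3`,
#'   `upper` (91st percentile).
#' @export
box_stats <- function(values) {
  q <- stats::quantile(values, c(0.09, 0.25, 0.5, 0.75, 0.91),
                       names = FALSE, na.rm = TRUE)
  data.frame(lower = q[1], q1 = q[2], median = q[3], q3 = q[4],
             upper = q[5])
}

#' Generate summary figures from a pipeline result bundle
#'
#' Writes the panels of the analysis: stage-wise boxplots of mean spot
#' intensity and ON fraction (median/IQR boxes, whiskers at the 9th and
#' 91st percentiles), the duration-output scatter with the LOWESS curve
#' and inflection, behaviour-class proportion bars per stage, the
#' complete-burst threshold-sweep curve and, when provided, the
#' RMSE-versus-interval curve.
#'
#' @param bundle result of [run_pipeline()].
#' @param outdir directory for the figure files (PDF).
#' @param rmse_table optional data.frame `interval`, `median_rmse` from
#'   [select_interval()].
#' @return Character vector of the files written.
#' @export
generate_report <- function(bundle, outdir, rmse_table = NULL) {
  need <- c("summary", "stage_stats", "classification", "sweep",
            "class_details")
  missing_parts <- need[!need %in% names(bundle)]
  if (length(missing_parts) > 0 ||
      is.null(bundle$classification) || nrow(bundle$classification) == 0)
    stop("report error: missing artefact(s): ",
         paste(c(missing_parts,
                 if (!is.null(bundle$classification) &&
                     nrow(bundle$classification) == 0) "classification"),
               collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  save_plot <- function(p, name, w = 6, h = 4) {
    f <- file.path(outdir, name)
    grDevices::pdf(f, width = w, height = h)
    print(p)
    grDevices::dev.off()
    files <<- c(files, f)
  }

  stage_box <- function(var, ylab) {
    bs <- do.call(rbind, lapply(split(bundle$summary[[var]],
                                      bundle$summary$stage), box_stats))
    bs$stage <- rownames(bs)
    ggplot2::ggplot(bs, ggplot2::aes(x = stage)) +
      ggplot2::geom_boxplot(ggplot2::aes(ymin = lower, lower = q1,
                                         middle = median, upper = q3,
                                         ymax = upper),
                            stat = "identity", fill = "grey85") +
      ggplot2::labs(x = "differentiation stage", y = ylab) +
      ggplot2::theme_classic()
  }
  save_plot(stage_box("mean_intensity", "mean spot intensity (a.u.)"),
            "stage_mean_intensity.pdf")
  save_plot(stage_box("on_fraction", "ON fraction"),
            "stage_on_fraction.pdf")

  cd <- bundle$class_details
  curve_df <- data.frame(x = cd$curve$grid, y = cd$curve$smoothed)
  p <- ggplot2::ggplot(bundle$classification,
                       ggplot2::aes(x = on_duration, y = output,
                                    colour = final_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(x = x, y = y), inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = cd$inflection$inflection_duration,
                        linetype = 2) +
    ggplot2::labs(x = "ON duration (min)",
                  y = "transcriptional output (a.u. min)") +
    ggplot2::theme_classic()
  save_plot(p, "duration_output.pdf")

  cls_tab <- as.data.frame(prop.table(table(
    stage = bundle$classification$stage,
    class = bundle$classification$final_class), 1))
  p <- ggplot2::ggplot(cls_tab,
                       ggplot2::aes(x = stage, y = Freq, fill = class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "differentiation stage", y = "proportion of cells") +
    ggplot2::theme_classic()
  save_plot(p, "class_proportions.pdf")

  p <- ggplot2::ggplot(bundle$sweep$table,
                       ggplot2::aes(x = threshold, y = n_complete)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = bundle$sweep$peak_threshold,
                        linetype = 2) +
    ggplot2::labs(x = "ON threshold (a.u.)", y = "complete bursts") +
    ggplot2::theme_classic()
  save_plot(p, "threshold_sweep.pdf")

  if (!is.null(rmse_table)) {
    p <- ggplot2::ggplot(rmse_table,
                         ggplot2::aes(x = interval, y = median_rmse)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "sampling interval", y = "median RMSE (a.u.)") +
      ggplot2::theme_classic()
    save_plot(p, "rmse_vs_interval.pdf")
  }
  files
}
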