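# End-to-end orchestration: simulate -> train -> predict -> smooth -> events
# -> georeference -> spatial indices, with a manifest for reproducibility.

#' Pipeline run configuration
#'
#' Flat key-value configuration, also readable from a JSON file via
#' [read_run_config()]. Two analysis modes mirror the two experiments the
#' method is built around: `"validate"` (annotated accelerometer data only;
#' emits the classifier performance report) and `"deploy"` (accelerometer +
#' GPS + an annotated observation window; emits events and spatial indices).
#' `"simulate"` generates a synthetic deployment on disk.
#'
#' @param mode `"simulate"`, `"validate"` or `"deploy"`.
#' @param out_dir output directory (created if missing).
#' @param accel_csv,labels_csv,gps_path input paths (as required by mode).
#' @param seed single integer seed driving all randomness.
#' @param rate_hz accelerometer sample rate.
#' @param n_scent,n_other,n_other_test,k_grid,folds,vote classifier design.
#' @param min_duration_s,georef_tolerance_s smoothing/eventing parameters.
#' @param mcp_percent,buffer_m,split_min spatial parameters.
#' @param clock_offset_s constant accel-to-GPS clock offset correction,
#'   seconds added to accelerometer times.
#' @param sim named list of [sim_config()] overrides (simulate mode).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("validate", "deploy", "simulate"),
                       out_dir = "scentmark_run",
                       accel_csv = NULL, labels_csv = NULL, gps_path = NULL,
                       seed = 1L, rate_hz = 50,
                       n_scent = 50, n_other = 500, n_other_test = 3000,
                       k_grid = seq(1L, 21L, by = 2L), folds = 5L,
                       vote = "majority",
                       min_duration_s = 2, georef_tolerance_s = 10,
                       mcp_percent = 95, buffer_m = 10, split_min = 10,
                       clock_offset_s = 0, sim = list()) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, accel_csv = accel_csv,
              labels_csv = labels_csv, gps_path = gps_path,
              seed = as.integer(seed), rate_hz = rate_hz, n_scent = n_scent,
              n_other = n_other, n_other_test = n_other_test,
              k_grid = as.integer(k_grid), folds = as.integer(folds),
              vote = vote, min_duration_s = min_duration_s,
              georef_tolerance_s = georef_tolerance_s,
              mcp_percent = mcp_percent, buffer_m = buffer_m,
              split_min = split_min, clock_offset_s = clock_offset_s,
              sim = sim)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file of configuration keys.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Run the scent-marking pipeline
#'
#' Executes every stage appropriate to the configured mode, writes each
#' intermediate artefact under `out_dir`, and returns a manifest recording
#' the package version, seed, parameters, per-stage record counts and an MD5
#' hash of every output file. Identical configuration and seed produce
#' byte-identical outputs. Missing GPS input in deploy mode degrades
#' gracefully: the pipeline completes through event extraction and flags the
#' spatial stages as skipped.
#'
#' @param config a [run_config()] (or a path to a JSON configuration).
#' @return The manifest (also written to `out_dir/manifest.json`),
#'   invisibly carrying the in-memory stage results as attribute `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$accel_csv, config$labels_csv, config$gps_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "scentmark",
                   version = as.character(utils::packageVersion("scentmark")),
                   mode = config$mode, seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("mode", "out_dir", "sim"))],
                   stages = list(), skipped = list(), files = list())
  results <- list()

  if (config$mode == "simulate") {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    sc <- simulate_scenario(cfg)
    write_accel_csv(sc$trace, file.path(config$out_dir, "accel.csv"))
    write_labels_csv(sc$labels, file.path(config$out_dir, "labels.csv"))
    write_gpx(sc$track, file.path(config$out_dir, "track.gpx"))
    truth <- sc$truth
    jsonlite::write_json(
      list(mark_locations = truth$mark_locations,
           foray_windows = truth$foray_windows),
      file.path(config$out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE)
    manifest$stages$simulate <- list(n_samples = length(sc$trace),
                                     n_label_intervals = nrow(sc$labels),
                                     n_fixes = nrow(sc$track),
                                     n_marks = nrow(truth$mark_locations))
    results$scenario <- sc
    return(finish_manifest(manifest, config$out_dir, results))
  }

  if (is.null(config$accel_csv) || is.null(config$labels_csv)) {
    stop("stage 'inputs': accel_csv and labels_csv are required in mode ",
         config$mode)
  }
  trace <- read_accel_csv(config$accel_csv, config$rate_hz)
  trace$t <- trace$t + config$clock_offset_s
  labels <- read_labels(config$labels_csv, collapse = TRUE)
  manifest$stages$inputs <- list(n_samples = length(trace),
                                 n_label_intervals = nrow(labels))

  # training/tuning restricted to the annotated span
  lab_span <- c(min(labels$start_s), max(labels$end_s))
  in_span <- trace$t >= lab_span[1] & trace$t < lab_span[2]
  obs_trace <- accel_trace(trace$t[in_span], trace$x[in_span],
                           trace$y[in_span], trace$z[in_span], trace$rate_hz)
  tk <- tune_k(obs_trace, labels, k_grid = config$k_grid,
               folds = config$folds, seed = config$seed,
               n_scent = config$n_scent, n_other = config$n_other,
               vote = config$vote)
  model <- knn_classifier(tk$training, tk$k_best, config$vote)
  utils::write.csv(tk$cv_table, file.path(config$out_dir, "cv_table.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$stages$train <- list(k_best = tk$k_best,
                                n_training = nrow(tk$training))
  results$model <- model

  if (config$mode == "validate") {
    testing <- build_testing_set(obs_trace, labels, tk$training,
                                 config$n_other_test, config$seed + 1L)
    pr <- knn_predict(model, testing, return_scores = TRUE)
    report <- evaluate(testing$class, pr$class, pr$scores)
    write_metrics(report, file.path(config$out_dir, "metrics.json"))
    write_metrics(report, file.path(config$out_dir, "metrics_per_class.csv"))
    manifest$stages$validate <- list(n_testing = nrow(testing),
                                     accuracy = report$accuracy,
                                     f1 = report$f1)
    results$report <- report
    return(finish_manifest(manifest, config$out_dir, results))
  }

  # deploy: predict the full trace, smooth, extract and georeference events
  pred <- knn_predict(model, trace)
  series <- smooth_modal(pred, trace$t)
  write_predictions_csv(series, file.path(config$out_dir, "series_1hz.csv"))
  events <- extract_events(series, config$min_duration_s)
  manifest$stages$predict <- list(n_samples = length(trace),
                                  n_bins = nrow(series),
                                  n_events = nrow(events))
  results$series <- series

  track <- NULL
  if (!is.null(config$gps_path)) {
    track <- project_track(read_gps(config$gps_path))
    events <- suppressWarnings(
      georeference(events, track, config$georef_tolerance_s))
  } else {
    events$located <- FALSE
    events$x_m <- NA_real_; events$y_m <- NA_real_
    events$lon <- NA_real_; events$lat <- NA_real_
    events$source_fix_t <- NA_real_
    manifest$skipped$georeference <- "no GPS input"
  }
  utils::write.csv(format_events(events),
                   file.path(config$out_dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  write_events_geojson(events, file.path(config$out_dir, "events.geojson"))
  results$events <- events
  deployment_h <- diff(range(trace$t)) / 3600
  manifest$stages$events <- list(
    n_events = nrow(events), n_located = sum(events$located),
    deployment_hours = round(deployment_h, 2),
    rate_per_hour = scent_mark_rate(nrow(events), deployment_h))

  located <- events[events$located, , drop = FALSE]
  if (is.null(track)) {
    manifest$skipped$spatial <- "no GPS input"
  } else if (nrow(located) < 3) {
    manifest$skipped$spatial <- sprintf(
      "only %d located scent marks (need >= 3 for a territory MCP)",
      nrow(located))
  } else {
    home <- mcp(cbind(track$x_m, track$y_m), config$mcp_percent)
    territory <- mcp(cbind(located$x_m, located$y_m), config$mcp_percent)
    ref_lon <- attr(track, "ref_lon"); ref_lat <- attr(track, "ref_lat")
    write_polygon_geojson(home, ref_lon, ref_lat,
                          file.path(config$out_dir, "home_range.geojson"),
                          list(kind = "home_range", percent = config$mcp_percent))
    write_polygon_geojson(territory, ref_lon, ref_lat,
                          file.path(config$out_dir, "territory.geojson"),
                          list(kind = "territory", percent = config$mcp_percent))
    ov <- overlap_proportion(home, territory)
    rv <- detect_revisits(located, config$buffer_m)
    fo <- detect_forays(track, territory, config$split_min)
    utils::write.csv(fo$forays, file.path(config$out_dir, "forays.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(rv$revisits, file.path(config$out_dir, "revisits.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(home_range_area_m2 = home$area_m2,
           territory_area_m2 = territory$area_m2,
           overlap_proportion = ov,
           n_revisits = nrow(rv$revisits),
           mean_revisit_interval_h = rv$mean_interval_h,
           foray_summary = unclass(fo$summary)),
      file.path(config$out_dir, "spatial_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    manifest$stages$spatial <- list(
      home_range_area_m2 = home$area_m2,
      territory_area_m2 = territory$area_m2,
      overlap_proportion = ov, n_revisits = nrow(rv$revisits),
      n_forays = fo$summary$n_forays)
    results$spatial <- list(home = home, territory = territory, overlap = ov,
                            revisits = rv, forays = fo)
  }
  finish_manifest(manifest, config$out_dir, results)
}

format_events <- function(events) {
  out <- events
  for (nm in c("start_s", "end_s", "duration_s", "x_m", "y_m", "lon", "lat",
               "source_fix_t")) {
    if (!is.null(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), "", fmt_num(out[[nm]]))
    }
  }
  out
}

finish_manifest <- function(manifest, out_dir, results) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$files <- lapply(files, function(f) {
    list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  attr(manifest, "results") <- results
  invisible(manifest)
}
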