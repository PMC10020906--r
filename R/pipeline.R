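default_pipeline_config <- function() {
  list(
    paths = list(gps = NULL, accel = NULL, diary = NULL, out = "results"),
    window = list(start = NULL, end = NULL),
    columns = list(gps = list(), accel = list(), diary = list()),
    motion = list(enabled = TRUE, epoch_s = 30),
    classifier = list(min_stop_s = 300, stop_radius_m = 100,
                      merge_gap_s = 120, motion_threshold = NULL,
                      gap_split_s = 1800),
    features = list(tz = "UTC", home_lat = NULL, home_lon = NULL,
                    mode_threshold_kmh = 20, dpa_buffer_m = 200),
    evaluation = list(overlap_frac = 0.5, max_trip_gap_s = 14400)
  )
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration file (or takes a list) and merges it over
#' the package defaults. See [run_pipeline()] for the recognised keys.
#'
#' @param config Path to a YAML file, a list, or `NULL` for pure defaults.
#' @return A complete configuration list.
#' @export
load_pipeline_config <- function(config = NULL) {
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file does not exist: ", config),
            class = "mobitrace_io_error")
    }
    yaml::read_yaml(config)
  } else {
    config
  }
  deep_merge(default_pipeline_config(), user)
}

#' Run the full mobility analysis pipeline
#'
#' Orchestrates every stage end to end: read the raw GPS (and, when
#' configured, accelerometer) CSVs, trim to the study window, preprocess
#' (de-duplication, motion score), run the stop/trip classification,
#' derive the daily mobility feature table, and — when a diary is
#' configured — evaluate the classification against it. Writes
#' `stops.csv`, `trips.csv`, `samples.csv` and `daily_features.csv` (plus
#' `confusion.csv` and `interval_report.csv` with a diary) to the output
#' directory and logs per-stage record counts.
#'
#' @param config A YAML path or config list ([load_pipeline_config()]).
#'   Keys: `paths` (gps, accel, diary, out), `window` (start, end),
#'   `columns` (per-reader column maps), `motion` (enabled, epoch_s),
#'   `classifier` (see [classifier_params()]), `features` (tz, home_lat/
#'   home_lon, mode_threshold_kmh, dpa_buffer_m), `evaluation`
#'   (overlap_frac, max_trip_gap_s).
#' @param use_motion Override of `motion$enabled`, e.g. from a CLI flag.
#' @return Invisibly, a list with `fit` (the `stop_go` object), `daily`,
#'   `clusters`, `evaluation` (`NULL` without a diary) and the written
#'   file paths.
#' @export
run_pipeline <- function(config, use_motion = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(use_motion)) cfg$motion$enabled <- use_motion
  if (is.null(cfg$paths$gps)) {
    abort("pipeline stage [input]: no GPS path configured",
          class = "mobitrace_config_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage [", name, "]: ", conditionMessage(e)),
            class = "mobitrace_pipeline_error", parent = e)
    })
  }

  gps <- stage("read gps", read_gps_records(
    cfg$paths$gps, do.call(gps_column_map, cfg$columns$gps)
  ))
  inform(paste0("pipeline: ", nrow(gps), " GPS fixes read"))
  accel <- NULL
  if (!is.null(cfg$paths$accel) && isTRUE(cfg$motion$enabled)) {
    accel <- stage("read accel", read_accel_records(
      cfg$paths$accel, do.call(accel_column_map, cfg$columns$accel)
    ))
    inform(paste0("pipeline: ", nrow(accel), " accelerometer samples read"))
  }
  diary <- NULL
  if (!is.null(cfg$paths$diary)) {
    diary <- stage("read diary", read_diary(
      cfg$paths$diary, do.call(diary_column_map, cfg$columns$diary)
    ))
    inform(paste0("pipeline: ", nrow(diary), " diary stops read"))
  }
  if (!is.null(cfg$window$start) && !is.null(cfg$window$end)) {
    gps <- stage("trim", trim_to_study_window(gps, cfg$window$start, cfg$window$end))
    if (!is.null(accel)) {
      accel <- stage("trim", trim_to_study_window(accel, cfg$window$start, cfg$window$end))
    }
    inform(paste0("pipeline: ", nrow(gps), " GPS fixes inside study window"))
  }

  params <- classifier_params(
    min_stop_s = cfg$classifier$min_stop_s,
    stop_radius_m = cfg$classifier$stop_radius_m,
    merge_gap_s = cfg$classifier$merge_gap_s,
    motion_threshold = cfg$classifier$motion_threshold,
    use_motion = isTRUE(cfg$motion$enabled),
    gap_split_s = cfg$classifier$gap_split_s
  )
  fit <- stage("classify", run_stop_go(gps, accel, params,
                                       epoch_s = cfg$motion$epoch_s))
  inform(paste0("pipeline: ", nrow(fit$stops), " stops, ",
                nrow(fit$trips), " trips"))

  home_coords <- NULL
  if (!is.null(cfg$features$home_lat) && !is.null(cfg$features$home_lon)) {
    home_coords <- c(cfg$features$home_lat, cfg$features$home_lon)
  }
  clusters <- stage("features", cluster_locations(fit$stops))
  daily <- stage("features", daily_features(
    fit$samples, fit$stops, fit$trips, clusters = clusters,
    tz = cfg$features$tz, home_coords = home_coords,
    mode_threshold_kmh = cfg$features$mode_threshold_kmh,
    dpa_buffer_m = cfg$features$dpa_buffer_m
  ))
  inform(paste0("pipeline: daily features for ", nrow(daily), " day(s)"))

  out_dir <- cfg$paths$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stops_out <- add_location_ids(fit$stops, clusters)
  home <- if (nrow(clusters)) {
    detect_home(clusters, fit$stops, tz = cfg$features$tz,
                home_coords = home_coords)
  } else NA_integer_
  stops_out$is_home <- !is.na(home) & stops_out$location_id %in% home
  files <- stage("write", write_results(stops_out, daily, out_dir))
  trips_path <- file.path(out_dir, "trips.csv")
  readr::write_csv(
    select(mode_split(fit$trips, cfg$features$mode_threshold_kmh), -"path"),
    trips_path, progress = FALSE
  )
  samples_path <- file.path(out_dir, "samples.csv")
  readr::write_csv(
    fit$samples[, c("timestamp", "lat", "lon", "label")],
    samples_path, progress = FALSE
  )
  files <- c(files, trips = trips_path, samples = samples_path)

  evaluation <- NULL
  if (!is.null(diary)) {
    evaluation <- stage("evaluate", benchmark_report(
      gps, accel, diary, params = params, epoch_s = cfg$motion$epoch_s,
      overlap_frac = cfg$evaluation$overlap_frac,
      max_trip_gap_s = cfg$evaluation$max_trip_gap_s
    ))
    conf_path <- file.path(out_dir, "confusion.csv")
    readr::write_csv(
      mutate(evaluation$comparison,
             configuration = ifelse(isTRUE(cfg$motion$enabled),
                                    "with motion score", "without motion score"),
             .before = 1),
      conf_path, progress = FALSE
    )
    iv_path <- file.path(out_dir, "interval_report.csv")
    readr::write_csv(
      bind_rows(
        mutate(evaluation$with_motion$intervals,
               configuration = "with motion score", .before = 1),
        mutate(evaluation$without_motion$intervals,
               configuration = "without motion score", .before = 1)
      ),
      iv_path, progress = FALSE
    )
    files <- c(files, confusion = conf_path, interval_report = iv_path)
  }
  invisible(list(fit = fit, daily = daily, clusters = clusters,
                 evaluation = evaluation, files = files))
}
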