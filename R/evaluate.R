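#' Ground-truth labels from a mobility diary
#'
#' Labels every GPS sample `"stop"` when its timestamp lies inside any
#' diary stop's closed interval `[begin, end]`, else `"trip"`. Samples
#' recorded on days the diary does not cover at all have no ground truth
#' and are labeled `NA`, so they drop out of per-sample metrics.
#'
#' @param gps Tibble of GPS fixes.
#' @param diary Validated diary tibble ([read_diary()]).
#' @return `gps` with an added `truth` column.
#' @export
ground_truth_labels <- function(gps, diary) {
  t <- ts_num(gps$timestamp)
  truth <- rep("trip", length(t))
  for (i in seq_len(nrow(diary))) {
    sel <- t >= ts_num(diary$begin[i]) & t <= ts_num(diary$end[i])
    truth[sel] <- "stop"
  }
  covered_days <- unique(c(
    lubridate::as_date(diary$begin), lubridate::as_date(diary$end)
  ))
  truth[!(lubridate::as_date(gps$timestamp) %in% covered_days)] <- NA_character_
  gps$truth <- truth
  gps
}

#' Per-sample classification metrics against ground truth
#'
#' Tallies the stop/trip confusion matrix (positive class = stop) and the
#' derived metrics: percent correct `100 (tp+tn)/N`, balanced accuracy
#' `(sensitivity + specificity)/2` and the F1 score `2tp/(2tp+fp+fn)`.
#' Pairs where either label is missing are excluded; a metric whose
#' denominator is zero is reported as `NA`, never as 0.
#'
#' @param predicted,truth Aligned character vectors of `"stop"`/`"trip"`
#'   labels.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `n`,
#'   `percent_correct`, `balanced_accuracy`, `f1`.
#' @export
sample_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth labels must be aligned",
          class = "mobitrace_contract_error")
  }
  ok <- !is.na(predicted) & !is.na(truth)
  predicted <- predicted[ok]; truth <- truth[ok]
  tp <- sum(predicted == "stop" & truth == "stop")
  tn <- sum(predicted == "trip" & truth == "trip")
  fp <- sum(predicted == "stop" & truth == "trip")
  fn <- sum(predicted == "trip" & truth == "stop")
  n <- tp + tn + fp + fn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn, n = n,
    percent_correct = if (n == 0) NA_real_ else 100 * (tp + tn) / n,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    f1 = ratio(2 * tp, 2 * tp + fp + fn)
  )
}

#' Interval-level matching of detected stops/trips against the diary
#'
#' Mirrors the interval accounting used to audit stop/trip classifiers: a
#' detected stop is *correct* when its temporal overlap with some diary
#' stop is at least `overlap_frac` of the shorter of the two durations; a
#' diary stop is *missed* when no detected stop overlaps it at all, and
#' *fragmented* when two or more detected stops overlap it (a single true
#' dwell split into several detections). Diary trips are the gaps between
#' consecutive diary stops shorter than `max_trip_gap_s` (longer gaps are
#' recording pauses, not trips); a diary trip is *missed* when no detected
#' trip overlaps it.
#'
#' @param detected_stops,detected_trips Interval tibbles from
#'   [run_stop_go()].
#' @param diary Validated diary tibble.
#' @param overlap_frac Correctness threshold as a fraction of the shorter
#'   interval (default 0.5).
#' @param max_trip_gap_s Longest diary gap still counted as a trip
#'   (default 4 h).
#' @return A one-row tibble: `diary_stops`, `detected_stops`,
#'   `correct_stops`, `missed_stops`, `fragmented_stops`, `diary_trips`,
#'   `detected_trips`, `missed_trips`.
#' @export
match_intervals <- function(detected_stops, detected_trips, diary,
                            overlap_frac = 0.5, max_trip_gap_s = 4 * 3600) {
  nd <- nrow(diary)
  ns <- nrow(detected_stops)
  ov <- matrix(0, nrow = ns, ncol = nd)
  if (ns > 0 && nd > 0) {
    for (i in seq_len(ns)) {
      ov[i, ] <- pmax(0, pmin(ts_num(detected_stops$end[i]), ts_num(diary$end)) -
                        pmax(ts_num(detected_stops$start[i]), ts_num(diary$begin)))
    }
  }
  correct <- 0L
  if (ns > 0 && nd > 0) {
    for (i in seq_len(ns)) {
      shorter <- pmin(detected_stops$duration_s[i],
                      ts_num(diary$end) - ts_num(diary$begin))
      if (any(ov[i, ] >= overlap_frac * shorter & shorter > 0)) {
        correct <- correct + 1L
      }
    }
  }
  overlaps_per_diary <- if (ns > 0 && nd > 0) colSums(ov > 0) else rep(0L, nd)
  missed <- sum(overlaps_per_diary == 0)
  fragmented <- sum(overlaps_per_diary >= 2)

  # diary trips: short-enough gaps between consecutive diary stops
  diary <- arrange(diary, .data$begin)
  trip_begin <- ts_num(diary$end[-nd]) ; trip_end <- ts_num(diary$begin[-1])
  if (nd < 2) { trip_begin <- numeric(0); trip_end <- numeric(0) }
  keep <- (trip_end - trip_begin) > 0 & (trip_end - trip_begin) <= max_trip_gap_s
  trip_begin <- trip_begin[keep]; trip_end <- trip_end[keep]
  nt <- length(trip_begin)
  missed_trips <- 0L
  if (nt > 0) {
    for (i in seq_len(nt)) {
      hit <- nrow(detected_trips) > 0 &&
        any(pmax(0, pmin(ts_num(detected_trips$end), trip_end[i]) -
                   pmax(ts_num(detected_trips$start), trip_begin[i])) > 0)
      if (!hit) missed_trips <- missed_trips + 1L
    }
  }
  tibble(
    diary_stops = nd,
    detected_stops = ns,
    correct_stops = correct,
    missed_stops = missed,
    fragmented_stops = fragmented,
    diary_trips = nt,
    detected_trips = nrow(detected_trips),
    missed_trips = missed_trips
  )
}

#' Side-by-side evaluation with and without the motion score
#'
#' Runs the full classifier twice on the same GPS input — once fusing the
#' accelerometer motion score, once purely spatially — and evaluates both
#' runs against the diary ground truth at sample level (percent correct,
#' balanced accuracy, F1) and interval level (stop counts, correct, missed
#' and fragmented stops, trip counts, missed trips).
#'
#' @param gps GPS fix tibble.
#' @param accel Accelerometer tibble (may be `NULL`; the motion column of
#'   the with-motion run is then empty and both runs coincide).
#' @param diary Validated diary tibble.
#' @param params [classifier_params()]; `use_motion` is overridden per run.
#' @param epoch_s Motion-score epoch length (seconds).
#' @param overlap_frac,max_trip_gap_s Passed to [match_intervals()].
#' @return An object of class `stop_go_eval`: a list with `with_motion`
#'   and `without_motion` sub-lists (`metrics`, `intervals`, `fit`), plus
#'   a `comparison` tibble in long metric/value form. Has [tidy()],
#'   [glance()] and `print()` methods.
#' @export
benchmark_report <- function(gps, accel, diary, params = classifier_params(),
                             epoch_s = 30, overlap_frac = 0.5,
                             max_trip_gap_s = 4 * 3600) {
  eval_one <- function(use_motion) {
    p <- params
    p$use_motion <- use_motion
    fit <- run_stop_go(gps, accel = if (use_motion) accel else NULL,
                       params = p, epoch_s = epoch_s)
    labeled <- ground_truth_labels(fit$samples, diary)
    metrics <- sample_metrics(labeled$label, labeled$truth)
    intervals <- match_intervals(fit$stops, fit$trips, diary,
                                 overlap_frac = overlap_frac,
                                 max_trip_gap_s = max_trip_gap_s)
    list(fit = fit, metrics = metrics, intervals = intervals)
  }
  wm <- eval_one(TRUE)
  wo <- eval_one(FALSE)
  long <- function(x) {
    tidyr::pivot_longer(bind_cols(x$metrics, x$intervals),
                        dplyr::everything(),
                        names_to = "metric", values_to = "value")
  }
  comparison <- full_join(
    rename(long(wm), with_motion = "value"),
    rename(long(wo), without_motion = "value"),
    by = "metric"
  )
  structure(
    list(with_motion = wm, without_motion = wo, comparison = comparison),
    class = "stop_go_eval"
  )
}

#' @export
print.stop_go_eval <- function(x, ...) {
  cat("Stop/trip evaluation against diary ground truth\n\n")
  print(as.data.frame(x$comparison), row.names = FALSE)
  invisible(x)
}

#' Replay the evaluation on a recorded field dataset
#'
#' Convenience wrapper for auditing the pipeline against an externally
#' recorded dataset (GPS + accelerometer + diary CSVs): reads the three
#' files, optionally trims to a study window, and runs
#' [benchmark_report()].
#'
#' @param gps_file,accel_file,diary_file CSV paths; `accel_file` may be
#'   `NULL`.
#' @param window Optional `c(start, end)` study window.
#' @param gps_map,accel_map,diary_map Column maps for the three dialects.
#' @param ... Passed to [benchmark_report()].
#' @return A `stop_go_eval` object.
#' @export
run_benchmark <- function(gps_file, accel_file = NULL, diary_file,
                          window = NULL,
                          gps_map = gps_column_map(),
                          accel_map = accel_column_map(),
                          diary_map = diary_column_map(), ...) {
  gps <- read_gps_records(gps_file, gps_map)
  accel <- if (!is.null(accel_file)) read_accel_records(accel_file, accel_map)
  diary <- read_diary(diary_file, diary_map)
  if (!is.null(window)) {
    gps <- trim_to_study_window(gps, window[1], window[2])
    if (!is.null(accel)) accel <- trim_to_study_window(accel, window[1], window[2])
  }
  benchmark_report(gps, accel, diary, ...)
}
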