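#' Remove duplicate GPS fixes
#'
#' Recording apps occasionally flush the same fix twice. Rows identical in
#' `(timestamp, lat, lon)` are collapsed to their first occurrence; two
#' fixes sharing a timestamp but differing in coordinates are both kept.
#' Idempotent.
#'
#' @param gps A time-sorted tibble of GPS fixes.
#' @return The tibble without exact duplicates; order preserved.
#' @export
deduplicate <- function(gps) {
  if (nrow(gps) <= 1) return(gps)
  key <- paste(ts_num(gps$timestamp), gps$lat, gps$lon, sep = "|")
  gps[!duplicated(key), , drop = FALSE]
}

#' Per-epoch motion score from 3-axis accelerometry
#'
#' Summarises raw accelerometer samples into a scalar score per fixed epoch
#' that describes how much physical motion the device underwent. The score
#' is the population standard deviation of the acceleration-vector magnitude
#' \eqn{\sqrt{a_x^2 + a_y^2 + a_z^2}} over the epoch's samples: it is zero
#' for a device at rest (gravity contributes a constant magnitude),
#' invariant under any fixed rotation of the device, and grows with carried
#' movement. Epochs are aligned to multiples of `epoch_s` on the epoch
#' clock; epochs with fewer than 2 samples score 0.
#'
#' @param accel Tibble of accelerometer samples (`timestamp`, `ax`, `ay`,
#'   `az`), time-sorted.
#' @param epoch_s Epoch length in seconds (default 30).
#' @return A tibble with columns `epoch_start` (POSIXct, UTC),
#'   `epoch_length` (seconds), `score` (>= 0) and `n_samples`.
#' @export
#' @examples
#' acc <- tibble::tibble(
#'   timestamp = as.POSIXct("2022-03-01", tz = "UTC") + 0:59,
#'   ax = 0, ay = 0, az = 9.81
#' )
#' motion_score(acc, epoch_s = 30) # at rest: all scores 0
motion_score <- function(accel, epoch_s = 30) {
  if (!is.numeric(epoch_s) || length(epoch_s) != 1 || epoch_s <= 0) {
    abort("epoch_s must be a positive number", class = "mobitrace_param_error")
  }
  if (nrow(accel) == 0) {
    abort("accelerometer input is empty", class = "mobitrace_empty_input")
  }
  t <- ts_num(accel$timestamp)
  mag <- sqrt(accel$ax^2 + accel$ay^2 + accel$az^2)
  epoch <- floor(t / epoch_s) * epoch_s
  grp <- factor(epoch, levels = unique(sort(epoch)))
  n <- as.integer(tapply(mag, grp, length))
  # population SD: deterministic even on 2-sample epochs
  s <- as.numeric(tapply(mag, grp, function(m) {
    if (length(m) < 2) 0 else sqrt(mean((m - mean(m))^2))
  }))
  tibble(
    epoch_start = lubridate::as_datetime(as.numeric(levels(grp)), tz = "UTC"),
    epoch_length = epoch_s,
    score = s,
    n_samples = n
  )
}

#' Attach the motion score to GPS fixes
#'
#' Each GPS sample receives the score of the epoch containing its
#' timestamp, or `NA` when no epoch covers it (no accelerometer coverage).
#' Downstream classification tolerates missing motion: fixes without a
#' score are treated exactly as in a motion-free run.
#'
#' @param gps Tibble of GPS fixes.
#' @param motion A motion-score tibble from [motion_score()], or `NULL` /
#'   empty for no accelerometer data.
#' @return `gps` with an added numeric `motion` column; timestamps and
#'   coordinates untouched.
#' @export
attach_motion <- function(gps, motion) {
  if (is.null(motion) || nrow(motion) == 0) {
    gps$motion <- NA_real_
    return(gps)
  }
  if (length(unique(motion$epoch_length)) > 1) {
    abort("motion series must have a single epoch length",
          class = "mobitrace_param_error")
  }
  epoch_s <- motion$epoch_length[1]
  idx <- match(
    floor(ts_num(gps$timestamp) / epoch_s) * epoch_s,
    ts_num(motion$epoch_start)
  )
  gps$motion <- motion$score[idx]
  gps
}
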