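#' Stop/trip classifier parameters
#'
#' Bundles the tunables of the stay-point classifier. A *stop* is a period
#' of more than `min_stop_s` seconds spent within a `stop_radius_m`-metre
#' radius; everything else is a *trip*. `merge_gap_s` controls the
#' aggregation-time merging of stops separated by a short gap;
#' `gap_split_s` breaks the record at recording gaps (phone off or
#' charging) so no interval spans one.
#'
#' @param min_stop_s Minimum stop duration, seconds, strict (default 300:
#'   a dwell of exactly 300 s is a trip).
#' @param stop_radius_m Stop radius in metres (default 100).
#' @param merge_gap_s Two stops separated by a shorter gap, with centroids
#'   within `stop_radius_m`, merge into one (default 120).
#' @param motion_threshold Motion-score value separating physical stillness
#'   from movement, in score units. `NULL` (default) derives it from the
#'   data as the geometric midpoint of the 10th and 90th percentiles of the
#'   positive epoch scores, which splits the rest/movement score clusters
#'   regardless of device-specific units.
#' @param use_motion Use the accelerometer motion score to suppress
#'   GPS-noise-induced stop fragmentation (default `TRUE`).
#' @param gap_split_s Recording gaps longer than this split the
#'   segmentation (default 1800).
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(min_stop_s = 300, stop_radius_m = 100,
                              merge_gap_s = 120, motion_threshold = NULL,
                              use_motion = TRUE, gap_split_s = 1800) {
  if (min_stop_s <= 0) abort("min_stop_s must be > 0", class = "mobitrace_param_error")
  if (stop_radius_m <= 0) abort("stop_radius_m must be > 0", class = "mobitrace_param_error")
  if (merge_gap_s < 0) abort("merge_gap_s must be >= 0", class = "mobitrace_param_error")
  structure(
    list(min_stop_s = min_stop_s, stop_radius_m = stop_radius_m,
         merge_gap_s = merge_gap_s, motion_threshold = motion_threshold,
         use_motion = use_motion, gap_split_s = gap_split_s),
    class = "classifier_params"
  )
}

#' @export
print.classifier_params <- function(x, ...) {
  cat("Stop/trip classifier parameters\n")
  cat("  min stop duration : >", x$min_stop_s, "s\n")
  cat("  stop radius       : ", x$stop_radius_m, "m\n")
  cat("  merge gap         : <", x$merge_gap_s, "s\n")
  cat("  motion threshold  : ",
      if (is.null(x$motion_threshold)) "adaptive (q10/q90 geometric midpoint)"
      else x$motion_threshold, "\n")
  cat("  use motion score  : ", x$use_motion, "\n")
  cat("  gap split         : >", x$gap_split_s, "s\n")
  invisible(x)
}

# scalar-fast haversine used inside the classification loop
hav_fast <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

# Adaptive threshold anchored on the at-rest score level. Life-space
# recordings are dwell-dominated, so the 25th percentile of positive epoch
# scores estimates the rest level; 4x that clears the rest scatter (~13%
# relative SD at 30-s epochs) while staying far below carried-movement
# scores, and the cap at the geometric midpoint between rest level and the
# maximum score guards movement-heavy records.
adaptive_motion_threshold <- function(scores) {
  s <- scores[!is.na(scores) & scores > 0]
  if (length(s) == 0) return(0)
  rest <- unname(quantile(s, 0.25, type = 7))
  min(4 * rest, sqrt(rest * max(s)))
}

#' Label every GPS sample as stop or trip
#'
#' Stay-point detection with a running centroid: a maximal run of
#' consecutive fixes all lying within `stop_radius_m` of the run's running
#' centroid, spanning strictly more than `min_stop_s` seconds, is a stop;
#' all other samples are trip. Recording gaps longer than `gap_split_s`
#' split the record into segments that are classified independently.
#'
#' When `use_motion` is on and motion scores are attached
#' ([attach_motion()]), trip-labeled samples lying between two stop runs
#' whose centroids are within `stop_radius_m` of each other are relabeled
#' stop when their motion score is at or below the motion threshold: a
#' physically still device with a brief GPS-noise excursion stays in one
#' stop instead of fragmenting into several. Samples whose score exceeds
#' the threshold are evidence of genuine movement and are never bridged;
#' samples with missing motion are treated as in a motion-free run.
#'
#' @param gps Sorted, de-duplicated tibble of fixes; a `motion` column is
#'   used when present.
#' @param params A [classifier_params()] object.
#' @return `gps` with added columns `label` (`"stop"`/`"trip"`), `bridged`
#'   (logical: relabeled by motion-score fragment suppression) and
#'   `segment` (integer recording-segment id).
#' @export
classify_samples <- function(gps, params = classifier_params()) {
  n <- nrow(gps)
  if (!"motion" %in% names(gps)) gps$motion <- NA_real_
  gps$label <- character(n)
  gps$bridged <- logical(n)
  gps$segment <- integer(n)
  if (n == 0) return(gps)
  t <- ts_num(gps$timestamp)
  la <- gps$lat; lo <- gps$lon
  seg <- cumsum(c(0, diff(t) > params$gap_split_s)) + 1L
  gps$segment <- seg

  thr <- params$motion_threshold
  if (params$use_motion && is.null(thr)) {
    thr <- adaptive_motion_threshold(unique(gps$motion))
  }

  label <- rep("trip", n)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    m <- length(idx)
    if (m == 1) { label[idx] <- "stop"; next }
    ts <- t[idx]; las <- la[idx]; los <- lo[idx]
    i <- 1L
    while (i <= m) {
      clat <- las[i]; clon <- los[i]; k <- 1L
      j <- i + 1L
      while (j <= m) {
        if (hav_fast(las[j], los[j], clat, clon) > params$stop_radius_m) break
        clat <- (clat * k + las[j]) / (k + 1)
        clon <- (clon * k + los[j]) / (k + 1)
        k <- k + 1L
        j <- j + 1L
      }
      if (ts[j - 1L] - ts[i] > params$min_stop_s) {
        members <- refine_stop_run(i:(j - 1L), ts, las, los, params)
        if (length(members) > 0) label[idx[members]] <- "stop"
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  gps$label <- label

  if (params$use_motion && any(!is.na(gps$motion))) {
    gps <- suppress_fragments(gps, thr, params)
  }
  gps
}

# Boundary refinement of a candidate stop run. The running-centroid rule
# keeps fixes until they leave the stop radius, so a departure drags the
# first ~radius metres of walking into the stop. Peel members off both
# ends that lie farther from the run centroid than a robust multiple of
# the run's core scatter (3.5 x median member distance, capped at the stop
# radius); iterate because the centroid tightens as edges peel. On
# noise-free data this recovers the true boundary to within one sample.
refine_stop_run <- function(members, ts, las, los, params) {
  repeat {
    if (length(members) == 0) return(integer(0))
    clat <- mean(las[members]); clon <- mean(los[members])
    d <- hav_fast(las[members], los[members], clat, clon)
    tol <- min(params$stop_radius_m, 3.5 * median(d))
    lo <- 1L; hi <- length(members)
    while (lo <= hi && d[lo] > tol) lo <- lo + 1L
    while (hi >= lo && d[hi] > tol) hi <- hi - 1L
    if (lo == 1L && hi == length(members)) break
    members <- members[seq.int(lo, length.out = max(0L, hi - lo + 1L))]
  }
  if (length(members) < 2 ||
      ts[members[length(members)]] - ts[members[1]] <= params$min_stop_s) {
    return(integer(0))
  }
  members
}

# motion-gated fragment suppression: relabel low-motion samples caught
# between two same-place stop runs. Iterates to a fixed point because a
# successful bridge can bring a third run into reach.
suppress_fragments <- function(gps, thr, params) {
  t <- ts_num(gps$timestamp)
  repeat {
    changed <- FALSE
    r <- rle(paste(gps$segment, gps$label))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    is_stop <- grepl("stop$", r$values)
    stop_runs <- which(is_stop)
    if (length(stop_runs) >= 2) {
      for (ri in seq_len(length(stop_runs) - 1L)) {
        a <- stop_runs[ri]; b <- stop_runs[ri + 1L]
        if (b != a + 2L) next                      # need exactly one trip run between
        ia <- starts[a]:ends[a]; ib <- starts[b]:ends[b]
        if (gps$segment[ia[1]] != gps$segment[ib[1]]) next
        ka <- ia[!gps$bridged[ia]]; kb <- ib[!gps$bridged[ib]]
        ca <- c(mean(gps$lat[ka]), mean(gps$lon[ka]))
        cb <- c(mean(gps$lat[kb]), mean(gps$lon[kb]))
        if (hav_fast(ca[1], ca[2], cb[1], cb[2]) > params$stop_radius_m) next
        between <- (ends[a] + 1L):(starts[b] - 1L)
        still <- !is.na(gps$motion[between]) & gps$motion[between] <= thr
        if (all(still)) {
          gps$label[between] <- "stop"
          gps$bridged[between] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  gps
}

#' Aggregate per-sample labels into stop and trip intervals
#'
#' Maximal constant-label runs become intervals. Stop runs whose member
#' span does not exceed `min_stop_s` are relabeled trip; consecutive stops
#' separated by a gap shorter than `merge_gap_s` with centroids within
#' `stop_radius_m` are merged into one stop. Interval boundaries abut: an
#' interval ends where the next one starts, so within each recording
#' segment the intervals tile the covered time span exactly.
#'
#' @param labeled Output of [classify_samples()] (fixes plus `label`,
#'   `bridged`, `segment`).
#' @param params A [classifier_params()] object.
#' @return A list with tibbles `stops` (stop_id, start, end, duration_s,
#'   centroid_lat, centroid_lon, member_count, segment) and `trips`
#'   (trip_id, start, end, duration_s, length_m, median_speed_kmh, n_fixes,
#'   segment, path list-column).
#' @export
aggregate_intervals <- function(labeled, params = classifier_params()) {
  need <- c("timestamp", "lat", "lon", "label", "segment")
  if (!all(need %in% names(labeled))) {
    abort("aggregate_intervals needs classify_samples() output",
          class = "mobitrace_contract_error")
  }
  if (!"bridged" %in% names(labeled)) labeled$bridged <- FALSE
  empty_stops <- tibble(
    stop_id = integer(), start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"), duration_s = numeric(),
    centroid_lat = numeric(), centroid_lon = numeric(),
    member_count = integer(), segment = integer()
  )
  empty_trips <- tibble(
    trip_id = integer(), start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"), duration_s = numeric(),
    length_m = numeric(), median_speed_kmh = numeric(), n_fixes = integer(),
    segment = integer(), path = list()
  )
  if (nrow(labeled) == 0) return(list(stops = empty_stops, trips = empty_trips))

  t <- ts_num(labeled$timestamp)
  lab <- labeled$label
  seg <- labeled$segment
  bridged <- labeled$bridged

  run_table <- function() {
    r <- rle(paste(seg, lab))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tibble(first = starts, last = ends,
           segment = seg[starts], label = lab[starts])
  }

  # pass 1: enforce strict minimum stop duration (whole-segment runs are
  # degenerate recordings and keep their label)
  runs <- run_table()
  for (i in seq_len(nrow(runs))) {
    if (runs$label[i] != "stop") next
    whole_seg <- sum(seg == runs$segment[i]) == (runs$last[i] - runs$first[i] + 1L)
    if (whole_seg) next
    if (t[runs$last[i]] - t[runs$first[i]] <= params$min_stop_s) {
      lab[runs$first[i]:runs$last[i]] <- "trip"
    }
  }

  # pass 2: gap/radius merge of neighbouring stops, to fixed point
  repeat {
    runs <- run_table()
    stop_i <- which(runs$label == "stop")
    changed <- FALSE
    if (length(stop_i) >= 2) {
      for (k in seq_len(length(stop_i) - 1L)) {
        a <- stop_i[k]; b <- stop_i[k + 1L]
        if (b != a + 2L) next
        if (runs$segment[a] != runs$segment[b]) next
        gap <- t[runs$first[b]] - t[runs$last[a]]
        if (gap >= params$merge_gap_s) next
        ia <- runs$first[a]:runs$last[a]; ib <- runs$first[b]:runs$last[b]
        ka <- ia[!bridged[ia]]; if (length(ka) == 0) ka <- ia
        kb <- ib[!bridged[ib]]; if (length(kb) == 0) kb <- ib
        dcent <- hav_fast(mean(labeled$lat[ka]), mean(labeled$lon[ka]),
                          mean(labeled$lat[kb]), mean(labeled$lon[kb]))
        if (dcent > params$stop_radius_m) next
        between <- (runs$last[a] + 1L):(runs$first[b] - 1L)
        lab[between] <- "stop"
        bridged[between] <- TRUE
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }

  runs <- run_table()
  # abutting boundaries: an interval ends where the next begins (within a
  # segment); the final interval of a segment ends at its last sample
  nr <- nrow(runs)
  b_start <- t[runs$first]
  b_end <- numeric(nr)
  for (i in seq_len(nr)) {
    if (i < nr && runs$segment[i + 1L] == runs$segment[i]) {
      b_end[i] <- t[runs$first[i + 1L]]
    } else {
      b_end[i] <- t[runs$last[i]]
    }
  }

  stops <- list(); trips <- list()
  for (i in seq_len(nr)) {
    members <- runs$first[i]:runs$last[i]
    if (runs$label[i] == "stop") {
      core <- members[!bridged[members]]
      if (length(core) == 0) core <- members
      stops[[length(stops) + 1L]] <- tibble(
        start = lubridate::as_datetime(b_start[i], tz = "UTC"),
        end = lubridate::as_datetime(b_end[i], tz = "UTC"),
        duration_s = b_end[i] - b_start[i],
        centroid_lat = mean(labeled$lat[core]),
        centroid_lon = mean(labeled$lon[core]),
        member_count = length(members),
        segment = runs$segment[i]
      )
    } else {
      path <- labeled[members, c("timestamp", "lat", "lon")]
      if (length(members) >= 2) {
        d <- haversine_m(labeled$lat[members[-length(members)]],
                         labeled$lon[members[-length(members)]],
                         labeled$lat[members[-1]], labeled$lon[members[-1]])
        dt <- diff(t[members])
        speed <- 3.6 * d[dt > 0] / dt[dt > 0]
        len <- sum(d)
        med_speed <- if (length(speed)) median(speed) else NA_real_
      } else {
        len <- 0; med_speed <- NA_real_
      }
      trips[[length(trips) + 1L]] <- tibble(
        start = lubridate::as_datetime(b_start[i], tz = "UTC"),
        end = lubridate::as_datetime(b_end[i], tz = "UTC"),
        duration_s = b_end[i] - b_start[i],
        length_m = len,
        median_speed_kmh = med_speed,
        n_fixes = length(members),
        segment = runs$segment[i],
        path = list(path)
      )
    }
  }
  stops <- if (length(stops)) bind_rows(stops) else empty_stops
  trips <- if (length(trips)) bind_rows(trips) else empty_trips
  if (nrow(stops)) stops <- mutate(stops, stop_id = row_number(), .before = 1)
  if (nrow(trips)) trips <- mutate(trips, trip_id = row_number(), .before = 1)
  list(stops = stops, trips = trips)
}

#' Run the full stop/trip segmentation
#'
#' Composition of the whole classification stage: de-duplication, motion
#' scoring of the accelerometer stream, score attachment, per-sample
#' classification and interval aggregation. With `use_motion = FALSE` (or
#' no accelerometer data) the accelerometer input is ignored entirely and
#' the classifier runs purely spatially.
#'
#' @param gps Tibble of GPS fixes (`timestamp`, `lat`, `lon`).
#' @param accel Optional tibble of accelerometer samples.
#' @param params A [classifier_params()] object.
#' @param epoch_s Motion-score epoch length, seconds (default 30).
#' @return An object of class `stop_go`: a list with `samples` (labeled
#'   fixes), `stops`, `trips` and `params`. Has [tidy()], [glance()],
#'   `print()` and [autoplot()] methods.
#' @export
run_stop_go <- function(gps, accel = NULL, params = classifier_params(),
                        epoch_s = 30) {
  gps <- deduplicate(arrange(gps, .data$timestamp))
  motion <- NULL
  if (params$use_motion && !is.null(accel) && nrow(accel) > 0) {
    motion <- motion_score(accel, epoch_s = epoch_s)
  }
  gps <- attach_motion(gps, motion)
  labeled <- classify_samples(gps, params)
  iv <- aggregate_intervals(labeled, params)
  # keep sample labels consistent with post-aggregation intervals
  labeled$label <- interval_label_at(iv$stops, iv$trips, labeled$timestamp,
                                     default = labeled$label)
  structure(
    list(samples = labeled, stops = iv$stops, trips = iv$trips,
         params = params),
    class = "stop_go"
  )
}

# label each instant by the interval containing it. Intervals abut (one
# ends where the next starts), so membership is half-open [start, end); a
# segment's final interval is closed to cover its last sample.
interval_label_at <- function(stops, trips, timestamps, default = "trip") {
  t <- ts_num(timestamps)
  out <- if (length(default) == length(t)) default else rep(default, length(t))
  iv <- bind_rows(
    if (nrow(stops)) mutate(stops[, c("start", "end", "segment")], label = "stop"),
    if (nrow(trips)) mutate(trips[, c("start", "end", "segment")], label = "trip")
  )
  if (is.null(iv) || nrow(iv) == 0) return(out)
  iv <- arrange(iv, .data$start)
  seg_last_end <- tapply(ts_num(iv$end), iv$segment, max)
  for (i in seq_len(nrow(iv))) {
    s <- ts_num(iv$start[i]); e <- ts_num(iv$end[i])
    closed <- e >= seg_last_end[[as.character(iv$segment[i])]]
    sel <- if (closed) t >= s & t <= e else t >= s & t < e
    out[sel] <- iv$label[i]
  }
  out
}

#' @export
print.stop_go <- function(x, ...) {
  cat("Stop & Go segmentation\n")
  cat("  samples :", nrow(x$samples), "\n")
  cat("  stops   :", nrow(x$stops), "\n")
  cat("  trips   :", nrow(x$trips), "\n")
  if (nrow(x$stops)) {
    cat("  median stop duration:",
        round(median(x$stops$duration_s) / 60, 1), "min\n")
  }
  invisible(x)
}
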