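#' Cluster stops into significant locations
#'
#' Greedy sequential clustering in time order: each stop joins the first
#' existing cluster whose centroid lies within `radius_m` of the stop's
#' centroid, otherwise it founds a new cluster. Cluster centroids are
#' dwell-weighted means of their member stops, updated as members join.
#'
#' @param stops Stop-interval tibble ([run_stop_go()]), time-ordered.
#' @param radius_m Cluster radius in metres (default 100, matching the stop
#'   radius).
#' @return A tibble of clusters: `location_id`, `centroid_lat`,
#'   `centroid_lon`, `total_dwell_s`, `visit_count` and `stop_ids`
#'   (list-column of member stop ids). The per-stop assignment (aligned
#'   with `stops` rows) is attached as attribute `"assignment"`.
#' @export
cluster_locations <- function(stops, radius_m = 100) {
  n <- nrow(stops)
  cl_lat <- numeric(0); cl_lon <- numeric(0); cl_dwell <- numeric(0)
  members <- list()
  assignment <- integer(n)
  for (i in seq_len(n)) {
    slat <- stops$centroid_lat[i]; slon <- stops$centroid_lon[i]
    dwell <- stops$duration_s[i]
    hit <- 0L
    if (length(cl_lat) > 0) {
      d <- haversine_m(cl_lat, cl_lon, slat, slon)
      w <- which(d <= radius_m)
      if (length(w) > 0) hit <- w[1]
    }
    if (hit == 0L) {
      cl_lat <- c(cl_lat, slat); cl_lon <- c(cl_lon, slon)
      cl_dwell <- c(cl_dwell, dwell)
      members[[length(members) + 1L]] <- i
      assignment[i] <- length(cl_lat)
    } else {
      tot <- cl_dwell[hit] + dwell
      cl_lat[hit] <- (cl_lat[hit] * cl_dwell[hit] + slat * dwell) / tot
      cl_lon[hit] <- (cl_lon[hit] * cl_dwell[hit] + slon * dwell) / tot
      cl_dwell[hit] <- tot
      members[[hit]] <- c(members[[hit]], i)
      assignment[i] <- hit
    }
  }
  ids <- if ("stop_id" %in% names(stops)) stops$stop_id else seq_len(n)
  out <- tibble(
    location_id = seq_along(cl_lat),
    centroid_lat = cl_lat,
    centroid_lon = cl_lon,
    total_dwell_s = cl_dwell,
    visit_count = map_int(members, length),
    stop_ids = map(members, function(m) ids[m])
  )
  attr(out, "assignment") <- assignment
  out
}

#' Attach location ids to a stop table
#'
#' @param stops Stop tibble used to build `clusters`.
#' @param clusters Output of [cluster_locations()].
#' @return `stops` with an added `location_id` column.
#' @export
add_location_ids <- function(stops, clusters) {
  stops$location_id <- attr(clusters, "assignment")
  if (is.null(stops$location_id)) {
    ids <- if ("stop_id" %in% names(stops)) stops$stop_id else seq_len(nrow(stops))
    lookup <- tidyr::unnest(clusters[, c("location_id", "stop_ids")],
                            "stop_ids")
    stops$location_id <- lookup$location_id[match(ids, lookup$stop_ids)]
  }
  stops
}

# seconds of overlap between interval [s, e] and the nightly window
# [night[1], night[2]) hours of every day it touches
night_overlap_s <- function(start, end, night = c(0, 6), tz = "UTC") {
  s <- ts_num(start); e <- ts_num(end)
  total <- 0
  day0 <- lubridate::as_date(lubridate::with_tz(start, tz))
  day1 <- lubridate::as_date(lubridate::with_tz(end, tz))
  for (d in seq(day0, day1, by = "day")) {
    d0 <- ts_num(lubridate::force_tz(lubridate::as_datetime(as.Date(d, origin = "1970-01-01")), tz))
    w0 <- d0 + night[1] * 3600
    w1 <- d0 + night[2] * 3600
    total <- total + max(0, min(e, w1) - max(s, w0))
  }
  total
}

#' Identify the home location
#'
#' Home is the location cluster with the greatest dwell time during night
#' hours (00:00-06:00 local by default); ties break by total dwell. When
#' no cluster has any night dwell the cluster with the greatest total dwell
#' is used and a warning is emitted. Configured home coordinates override
#' the dwell heuristic: the nearest cluster within `radius_m` is chosen.
#'
#' @param clusters Output of [cluster_locations()].
#' @param stops The stop tibble the clusters were built from.
#' @param night Night window as `c(start_hour, end_hour)` (default 0-6).
#' @param tz Time zone for the night window (default `"UTC"`).
#' @param home_coords Optional `c(lat, lon)` of the known home address.
#' @param radius_m Match radius for `home_coords` (default 100).
#' @return The `location_id` of the home cluster (or `NA` if
#'   `home_coords` matches no cluster).
#' @export
detect_home <- function(clusters, stops, night = c(0, 6), tz = "UTC",
                        home_coords = NULL, radius_m = 100) {
  if (nrow(clusters) == 0) return(NA_integer_)
  if (!is.null(home_coords)) {
    d <- haversine_m(clusters$centroid_lat, clusters$centroid_lon,
                     home_coords[1], home_coords[2])
    if (min(d) > radius_m) {
      warn("no location cluster within radius of configured home coordinates")
      return(NA_integer_)
    }
    return(clusters$location_id[which.min(d)])
  }
  assignment <- attr(clusters, "assignment")
  night_by_stop <- map_dbl(seq_len(nrow(stops)), function(i) {
    night_overlap_s(stops$start[i], stops$end[i], night = night, tz = tz)
  })
  night_dwell <- vapply(clusters$location_id, function(id) {
    sum(night_by_stop[assignment == id])
  }, numeric(1))
  if (all(night_dwell == 0)) {
    warn("no night-time dwell at any location; falling back to total dwell")
    return(clusters$location_id[which.max(clusters$total_dwell_s)])
  }
  ord <- order(-night_dwell, -clusters$total_dwell_s)
  clusters$location_id[ord[1]]
}

#' Split trips into foot/bike vs vehicle
#'
#' A trip is classed `vehicle` when its median leg speed strictly exceeds
#' `threshold_kmh`, else `foot_bike` (ties and single-fix trips, which
#' have no leg speed, fall to `foot_bike`; single-fix trips warn).
#'
#' @param trips Trip tibble with `median_speed_kmh` and `n_fixes`.
#' @param threshold_kmh Speed threshold in km/h (default 20).
#' @return `trips` with an added `mode` column.
#' @export
mode_split <- function(trips, threshold_kmh = 20) {
  if (nrow(trips) == 0) {
    trips$mode <- character(0)
    return(trips)
  }
  if (any(trips$n_fixes < 2)) {
    warn("trip(s) with a single fix classed foot_bike (no speed available)")
  }
  trips$mode <- ifelse(
    !is.na(trips$median_speed_kmh) & trips$median_speed_kmh > threshold_kmh,
    "vehicle", "foot_bike"
  )
  trips
}

# origin/destination location of each trip, via the stops that abut it in
# time; trips at a recording edge (no adjacent stop) get NA endpoints
trip_endpoints <- function(trips, stops, clusters) {
  stops <- add_location_ids(stops, clusters)
  from <- rep(NA_integer_, nrow(trips))
  to <- rep(NA_integer_, nrow(trips))
  if (nrow(stops)) {
    from <- stops$location_id[match(ts_num(trips$start), ts_num(stops$end))]
    to <- stops$location_id[match(ts_num(trips$end), ts_num(stops$start))]
  }
  key <- ifelse(
    is.na(from) | is.na(to), NA_character_,
    paste(pmin(from, to), pmax(from, to), sep = "-")
  )
  tibble(trip_id = trips$trip_id, from_loc = from, to_loc = to, key = key)
}

#' Percentage of revisited (identical) trips
#'
#' Trips are keyed by the unordered pair of their origin and destination
#' location clusters; a trip is *revisited* when its key occurs at least
#' twice in the study. Trips without an adjacent stop on either side
#' (recording edges) are excluded from numerator and denominator.
#'
#' @param trips,stops Interval tibbles from [run_stop_go()].
#' @param clusters Output of [cluster_locations()]; computed from `stops`
#'   when `NULL`.
#' @return Percentage in \[0, 100\], or `NA` when no trip has both
#'   endpoints.
#' @export
revisited_paths_pct <- function(trips, stops, clusters = NULL) {
  if (is.null(clusters)) clusters <- cluster_locations(stops)
  ep <- trip_endpoints(trips, stops, clusters)
  keys <- ep$key[!is.na(ep$key)]
  if (length(keys) == 0) return(NA_real_)
  counts <- table(keys)
  100 * sum(counts[keys] >= 2) / length(keys)
}

overlap_s <- function(start, end, w0, w1) {
  pmax(0, pmin(ts_num(end), w1) - pmax(ts_num(start), w0))
}

#' Daily mobility feature table
#'
#' Computes, for every day of the study, the full mobility-variable
#' catalogue: distances from home, convex-hull metrics, robust standard
#' ellipse, buffered daily path area, revisited life space, location
#' counts, time budgets (at home, out of home, on foot/bike, in vehicle),
#' first-move time, most-active time of day, revisited-path percentage and
#' location entropy. Days are cut at local midnight of `tz`; intervals
#' spanning midnight contribute their within-day overlap to each day's
#' time budgets. A day inside the study range with no GPS data yields an
#' all-missing row.
#'
#' @param gps Labeled or raw GPS fix tibble.
#' @param stops,trips Interval tibbles from [run_stop_go()].
#' @param clusters Optional [cluster_locations()] output (recomputed when
#'   `NULL`).
#' @param home Optional `location_id` of home; detected via
#'   [detect_home()] when `NULL`.
#' @param tz Time zone for day boundaries and time-of-day bins.
#' @param home_coords Optional `c(lat, lon)` home override.
#' @param mode_threshold_kmh Foot/bike vs vehicle speed threshold.
#' @param dpa_buffer_m Daily-path-area buffer (default 200 m).
#' @return A tibble with one row per day; see the package vignette for the
#'   column dictionary.
#' @export
daily_features <- function(gps, stops, trips, clusters = NULL, home = NULL,
                           tz = "UTC", home_coords = NULL,
                           mode_threshold_kmh = 20, dpa_buffer_m = 200) {
  if (nrow(gps) == 0) {
    abort("no GPS samples", class = "mobitrace_empty_input")
  }
  if (is.null(clusters)) clusters <- cluster_locations(stops)
  if (is.null(home)) {
    home <- if (nrow(clusters)) {
      detect_home(clusters, stops, tz = tz, home_coords = home_coords)
    } else NA_integer_
  }
  stops <- add_location_ids(stops, clusters)
  stops$is_home <- !is.na(home) & stops$location_id %in% home
  trips <- mode_split(trips, threshold_kmh = mode_threshold_kmh)
  ep <- trip_endpoints(trips, stops, clusters)
  key_counts <- table(ep$key[!is.na(ep$key)])
  rls <- revisited_life_space(gps, tz = tz)
  home_lat <- if (!is.na(home)) clusters$centroid_lat[clusters$location_id == home] else NA_real_
  home_lon <- if (!is.na(home)) clusters$centroid_lon[clusters$location_id == home] else NA_real_

  dates <- lubridate::as_date(lubridate::with_tz(gps$timestamp, tz))
  days <- seq(min(dates), max(dates), by = "day")

  rows <- lapply(days, function(d) {
    w0 <- ts_num(lubridate::force_tz(lubridate::as_datetime(d), tz))
    w1 <- w0 + 86400
    day_gps <- gps[dates == d, , drop = FALSE]
    row <- tibble(
      date = d,
      n_samples = nrow(day_gps),
      max_distance_from_home_m = NA_real_,
      avg_distance_from_home_m = NA_real_,
      ellipse_area_m2 = NA_real_,
      hull_perimeter_m = NA_real_, hull_area_m2 = NA_real_,
      hull_compactness = NA_real_,
      revisited_life_space_pct = NA_real_,
      daily_path_area_m2 = NA_real_,
      n_locations = NA_integer_, n_revisited_locations = NA_integer_,
      n_unique_locations = NA_integer_,
      time_at_home_s = NA_real_, time_out_of_home_s = NA_real_,
      time_foot_bike_s = NA_real_, time_vehicle_s = NA_real_,
      first_move_time = as.POSIXct(NA, tz = tz),
      time_most_moved = NA_character_,
      revisited_paths_pct = NA_real_,
      location_entropy = NA_real_
    )
    if (nrow(day_gps) == 0) return(row)

    if (!is.na(home)) {
      dist_home <- haversine_m(day_gps$lat, day_gps$lon, home_lat, home_lon)
      row$max_distance_from_home_m <- max(dist_home)
      row$avg_distance_from_home_m <- mean(dist_home)
    }
    hull <- convex_hull_metrics(day_gps)
    row$hull_perimeter_m <- hull$hull_perimeter_m
    row$hull_area_m2 <- hull$hull_area_m2
    row$hull_compactness <- hull$hull_compactness
    row$ellipse_area_m2 <- standard_ellipse_area(day_gps)
    row$revisited_life_space_pct <- rls$revisited_pct[match(d, rls$date)]

    s_ov <- overlap_s(stops$start, stops$end, w0, w1)
    day_stops <- stops[s_ov > 0, , drop = FALSE]
    s_ov <- s_ov[s_ov > 0]
    t_ov <- overlap_s(trips$start, trips$end, w0, w1)
    day_trips <- trips[t_ov > 0, , drop = FALSE]
    t_ov <- t_ov[t_ov > 0]

    row$n_locations <- nrow(day_stops)
    row$n_unique_locations <- length(unique(day_stops$location_id))
    visit_lookup <- setNames(clusters$visit_count, clusters$location_id)
    row$n_revisited_locations <-
      sum(visit_lookup[as.character(day_stops$location_id)] >= 2)
    row$time_at_home_s <- sum(s_ov[day_stops$is_home])
    covered <- sum(s_ov) + sum(t_ov)
    row$time_out_of_home_s <- covered - row$time_at_home_s
    row$time_foot_bike_s <- sum(t_ov[day_trips$mode == "foot_bike"])
    row$time_vehicle_s <- sum(t_ov[day_trips$mode == "vehicle"])

    if (nrow(day_trips) > 0) {
      row$first_move_time <- lubridate::with_tz(
        lubridate::as_datetime(min(pmax(ts_num(day_trips$start), w0))), tz
      )
      starts_in_day <- day_trips[ts_num(day_trips$start) >= w0 &
                                   ts_num(day_trips$start) < w1, , drop = FALSE]
      if (nrow(starts_in_day) > 0) {
        h <- secs_of_day(starts_in_day$start, tz) / 3600
        bins <- c(morning = sum(h >= 5 & h < 11),
                  noon = sum(h >= 11 & h < 17),
                  evening = sum(h >= 17 & h < 23))
        if (any(bins > 0)) row$time_most_moved <- names(bins)[which.max(bins)]
      }
      paths <- map(seq_len(nrow(day_trips)), function(i) {
        p <- day_trips$path[[i]]
        p[ts_num(p$timestamp) >= w0 & ts_num(p$timestamp) < w1, , drop = FALSE]
      })
      row$daily_path_area_m2 <- daily_path_area(paths, buffer_m = dpa_buffer_m)
      day_keys <- ep$key[match(day_trips$trip_id, ep$trip_id)]
      day_keys <- day_keys[!is.na(day_keys)]
      if (length(day_keys) > 0) {
        row$revisited_paths_pct <-
          100 * sum(key_counts[day_keys] >= 2) / length(day_keys)
      }
    } else {
      row$daily_path_area_m2 <- 0
    }
    if (nrow(day_stops) > 0) {
      dwell_by_loc <- tapply(s_ov, day_stops$location_id, sum)
      row$location_entropy <- location_entropy(as.numeric(dwell_by_loc))
    }
    row
  })
  bind_rows(rows)
}
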