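#' Default location set for simulated studies
#'
#' A home plus four frequently visited places spread 0.5-3 km apart,
#' roughly the spatial scale of day-to-day mobility in a mid-sized town.
#'
#' @return A tibble with `name`, `lat`, `lon`, `is_home`.
#' @export
sim_locations <- function() {
  tibble(
    name = c("home", "market", "park", "clinic", "friend"),
    lat = c(48.1374, 48.1421, 48.1329, 48.1460, 48.1265),
    lon = c(11.5755, 11.5829, 11.5650, 11.5701, 11.5902),
    is_home = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the recording set-up of a smartphone mobility study:
#' GPS fixes every 10 s with ~10 m isotropic position noise, a 1 Hz 3-axis
#' accelerometer whose magnitude scatter differs between an at-rest device
#' and one carried while moving, dwells of at least 10 minutes at a small
#' set of recurring locations, and trips at pedestrian/bicycle or vehicle
#' speeds between them.
#'
#' @param seed Integer RNG seed; the same seed and config reproduce the
#'   study exactly.
#' @param n_days Number of study days (default 7).
#' @param locations Location tibble (see [sim_locations()]); exactly one
#'   row flagged `is_home`.
#' @param trips_per_day Round trips scheduled per day (default 3; the last
#'   trip returns home).
#' @param dwell_range_s Range of away-dwell durations, seconds (default
#'   600-5400: all dwells are genuine stops, i.e. longer than 5 min).
#' @param p_vehicle Probability a trip is made by vehicle (default 0.3).
#' @param speed_foot_kmh,speed_vehicle_kmh Speed ranges per mode, km/h.
#' @param gps_noise_sigma Isotropic GPS position noise, metres (default 10).
#' @param gps_interval_s GPS sampling interval, seconds (default 10).
#' @param accel_rate_hz Accelerometer rate, Hz (default 1).
#' @param rest_accel_sigma,move_accel_sigma Accelerometer magnitude noise
#'   (device units ~ m/s^2) at rest vs while moving (defaults 0.05 / 0.8).
#' @param gravity Constant magnitude offset (default 9.81).
#' @param dropout_prob Probability a scheduled GPS fix is lost (default
#'   0.02).
#' @param day_start,day_end Daily recording window, `"HH:MM:SS"` (default
#'   08:00-20:00; phones charge at home overnight, so no samples are
#'   recorded outside the window).
#' @param start_date First study day (default `"2022-03-01"`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_days = 7, locations = sim_locations(),
                       trips_per_day = 3, dwell_range_s = c(600, 5400),
                       p_vehicle = 0.3, speed_foot_kmh = c(3, 15),
                       speed_vehicle_kmh = c(25, 60), gps_noise_sigma = 10,
                       gps_interval_s = 10, accel_rate_hz = 1,
                       rest_accel_sigma = 0.05, move_accel_sigma = 0.8,
                       gravity = 9.81, dropout_prob = 0.02,
                       day_start = "08:00:00", day_end = "20:00:00",
                       start_date = "2022-03-01") {
  stopifnot(
    gps_interval_s > 0, accel_rate_hz > 0, rest_accel_sigma > 0,
    move_accel_sigma > 0, gps_noise_sigma >= 0,
    dropout_prob >= 0, dropout_prob <= 1,
    p_vehicle >= 0, p_vehicle <= 1, sum(locations$is_home) == 1
  )
  structure(
    list(seed = seed, n_days = n_days, locations = locations,
         trips_per_day = trips_per_day, dwell_range_s = dwell_range_s,
         p_vehicle = p_vehicle, speed_foot_kmh = speed_foot_kmh,
         speed_vehicle_kmh = speed_vehicle_kmh,
         gps_noise_sigma = gps_noise_sigma, gps_interval_s = gps_interval_s,
         accel_rate_hz = accel_rate_hz, rest_accel_sigma = rest_accel_sigma,
         move_accel_sigma = move_accel_sigma, gravity = gravity,
         dropout_prob = dropout_prob, day_start = day_start,
         day_end = day_end, start_date = start_date),
    class = "sim_config"
  )
}

# metres offset -> degrees at a given latitude (small-displacement)
offset_deg <- function(lat, dx_m, dy_m) {
  list(dlat = dy_m / 111320, dlon = dx_m / (111320 * cos(lat * pi / 180)))
}

#' Simulate a complete mobility study
#'
#' Generates a seeded synthetic study: a daily schedule alternating dwells
#' at the configured locations with straight-line trips at mode-sampled
#' speeds, GPS fixes (true position plus isotropic Gaussian noise, with
#' dropout), a 1 Hz accelerometer trace whose magnitude scatter switches
#' between the at-rest and in-motion regimes, the dwell diary (ground
#' truth) and per-day truth bookkeeping. Identical seed and configuration
#' reproduce the study bit for bit.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_study`: list with `gps` (fixes
#'   including a `truth` label column), `accel`, `diary`, `truth_daily`
#'   and the `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  loc <- config$locations
  home_i <- which(loc$is_home)
  day0 <- lubridate::as_datetime(paste(config$start_date, config$day_start),
                                 tz = "UTC")
  day_len <- as.numeric(lubridate::hms(config$day_end)) -
    as.numeric(lubridate::hms(config$day_start))
  if (day_len <= 0) abort("day_end must be after day_start",
                          class = "mobitrace_config_error")

  empty <- list(
    gps = tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                 lat = numeric(), lon = numeric(), truth = character()),
    accel = tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                   ax = numeric(), ay = numeric(), az = numeric()),
    diary = tibble(begin = as.POSIXct(character(), tz = "UTC"),
                   end = as.POSIXct(character(), tz = "UTC"),
                   lat = numeric(), lon = numeric(), address = character()),
    truth_daily = tibble(date = as.Date(character()), n_stops = integer(),
                         n_trips = integer(), time_at_home_s = numeric(),
                         time_out_of_home_s = numeric(),
                         first_move_time = as.POSIXct(character(), tz = "UTC")),
    config = config
  )
  if (config$n_days == 0) return(structure(empty, class = "synthetic_study"))

  withr::with_seed(config$seed, {
    segments <- list()  # per piece: type, t0, t1, loc index / path endpoints, speed
    diary <- list(); truth_daily <- list()
    for (d in seq_len(config$n_days)) {
      t0 <- ts_num(day0) + (d - 1) * 86400
      t_end <- t0 + day_len
      # destinations: wander between non-home places, final leg returns home
      n_trips <- config$trips_per_day
      dests <- integer(0)
      cur <- home_i
      if (n_trips >= 1) {
        for (k in seq_len(max(0, n_trips - 1))) {
          cand <- setdiff(seq_len(nrow(loc)), cur)
          cur <- if (length(cand) == 1) cand else sample(cand, 1)
          dests <- c(dests, cur)
        }
        if (cur != home_i) dests <- c(dests, home_i) # return home if away
      }
      day_segments <- list()
      cur <- home_i
      t <- t0
      first_move <- NA_real_
      for (k in seq_along(dests)) {
        dwell <- runif(1, config$dwell_range_s[1], config$dwell_range_s[2])
        dwell_end <- min(t + dwell, t_end)
        day_segments[[length(day_segments) + 1]] <-
          list(type = "dwell", t0 = t, t1 = dwell_end, loc = cur)
        t <- dwell_end
        if (t >= t_end) break
        to <- dests[k]
        dist <- haversine_m(loc$lat[cur], loc$lon[cur], loc$lat[to], loc$lon[to])
        vehicle <- runif(1) < config$p_vehicle
        rng <- if (vehicle) config$speed_vehicle_kmh else config$speed_foot_kmh
        speed <- runif(1, rng[1], rng[2]) / 3.6
        dur <- dist / speed
        if (dur > day_len) {
          abort("a single trip is longer than the recording day",
                class = "mobitrace_config_error")
        }
        # only travel if the destination dwell still fits the day: the
        # diary must never contain a truncated sub-minimum dwell
        if (t + dur + config$dwell_range_s[1] > t_end) break
        day_segments[[length(day_segments) + 1]] <-
          list(type = "trip", t0 = t, t1 = t + dur, from = cur, to = to,
               vehicle = vehicle)
        if (is.na(first_move)) first_move <- t
        t <- t + dur
        cur <- to
      }
      if (t < t_end) {
        last <- day_segments[[length(day_segments)]]
        if (last$type == "dwell" && last$loc == cur) {
          day_segments[[length(day_segments)]]$t1 <- t_end
        } else {
          day_segments[[length(day_segments) + 1]] <-
            list(type = "dwell", t0 = t, t1 = t_end, loc = cur)
        }
      }
      dwells <- keep(day_segments, ~ .x$type == "dwell" && .x$t1 > .x$t0)
      trips <- keep(day_segments, ~ .x$type == "trip")
      diary[[d]] <- tibble(
        begin = lubridate::as_datetime(map_dbl(dwells, "t0"), tz = "UTC"),
        end = lubridate::as_datetime(map_dbl(dwells, "t1"), tz = "UTC"),
        lat = loc$lat[map_int(dwells, "loc")],
        lon = loc$lon[map_int(dwells, "loc")],
        address = loc$name[map_int(dwells, "loc")]
      )
      home_dwell <- sum(map_dbl(keep(dwells, ~ .x$loc == home_i),
                                ~ .x$t1 - .x$t0))
      truth_daily[[d]] <- tibble(
        date = lubridate::as_date(lubridate::as_datetime(t0)),
        n_stops = length(dwells),
        n_trips = length(trips),
        time_at_home_s = home_dwell,
        time_out_of_home_s = day_len - home_dwell,
        first_move_time = lubridate::as_datetime(first_move, tz = "UTC")
      )
      segments <- c(segments, day_segments)
    }

    # true position at arbitrary instants, from the piecewise schedule
    true_pos <- function(tq) {
      latv <- numeric(length(tq)); lonv <- numeric(length(tq))
      for (s in segments) {
        sel <- tq >= s$t0 & tq <= s$t1
        if (!any(sel)) next
        if (s$type == "dwell") {
          latv[sel] <- loc$lat[s$loc]; lonv[sel] <- loc$lon[s$loc]
        } else {
          frac <- (tq[sel] - s$t0) / (s$t1 - s$t0)
          latv[sel] <- loc$lat[s$from] + frac * (loc$lat[s$to] - loc$lat[s$from])
          lonv[sel] <- loc$lon[s$from] + frac * (loc$lon[s$to] - loc$lon[s$from])
        }
      }
      list(lat = latv, lon = lonv)
    }
    in_trip <- function(tq) {
      out <- rep(FALSE, length(tq))
      for (s in segments) {
        if (s$type == "trip") out[tq > s$t0 & tq < s$t1] <- TRUE
      }
      out
    }

    gps_t <- unlist(lapply(seq_len(config$n_days), function(d) {
      t0 <- ts_num(day0) + (d - 1) * 86400
      seq(t0, t0 + day_len, by = config$gps_interval_s)
    }))
    keep_fix <- runif(length(gps_t)) >= config$dropout_prob
    gps_t <- gps_t[keep_fix]
    pos <- true_pos(gps_t)
    noise_x <- rnorm(length(gps_t), 0, config$gps_noise_sigma)
    noise_y <- rnorm(length(gps_t), 0, config$gps_noise_sigma)
    off <- offset_deg(pos$lat, noise_x, noise_y)
    gps <- tibble(
      timestamp = lubridate::as_datetime(gps_t, tz = "UTC"),
      lat = pos$lat + off$dlat,
      lon = pos$lon + off$dlon
    )

    acc_step <- 1 / config$accel_rate_hz
    acc_t <- unlist(lapply(seq_len(config$n_days), function(d) {
      t0 <- ts_num(day0) + (d - 1) * 86400
      seq(t0, t0 + day_len, by = acc_step)
    }))
    moving <- in_trip(acc_t)
    sigma <- ifelse(moving, config$move_accel_sigma, config$rest_accel_sigma)
    n_acc <- length(acc_t)
    accel <- tibble(
      timestamp = lubridate::as_datetime(acc_t, tz = "UTC"),
      ax = rnorm(n_acc, 0, 0.3 * sigma),
      ay = rnorm(n_acc, 0, 0.3 * sigma),
      az = config$gravity + rnorm(n_acc, 0, sigma)
    )

    diary <- bind_rows(diary)
    gps <- ground_truth_labels(gps, diary)
    structure(
      list(gps = gps, accel = accel, diary = diary,
           truth_daily = bind_rows(truth_daily), config = config),
      class = "synthetic_study"
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic mobility study (seed ", x$config$seed, ")\n", sep = "")
  cat("  days  :", x$config$n_days, "\n")
  cat("  fixes :", nrow(x$gps), " accel samples:", nrow(x$accel), "\n")
  cat("  diary :", nrow(x$diary), "stops\n")
  invisible(x)
}

#' Degrade a synthetic study with extra noise and position bursts
#'
#' Models suboptimal GPS reception (narrow streets, rural multipath):
#' adds zero-mean Gaussian noise of `extra_noise_sigma` metres to every
#' fix, plus heavy-tailed position bursts — with probability `burst_prob`
#' a fix is displaced in a uniform random direction by a distance drawn
#' uniformly from 0 to `burst_max_m`. Ground truth (diary, truth labels,
#' truth bookkeeping) is unchanged.
#'
#' @param study A `synthetic_study`.
#' @param extra_noise_sigma Extra Gaussian noise, metres (default 0).
#' @param burst_prob Per-fix burst probability (default 0).
#' @param burst_max_m Maximum burst displacement (default 300 m).
#' @param seed Seed for the degradation stream (default: study seed + 1).
#' @return The degraded `synthetic_study`.
#' @export
degrade <- function(study, extra_noise_sigma = 0, burst_prob = 0,
                    burst_max_m = 300, seed = study$config$seed + 1) {
  if (extra_noise_sigma == 0 && burst_prob == 0) return(study)
  n <- nrow(study$gps)
  if (n == 0) return(study)
  withr::with_seed(seed, {
    dx <- rnorm(n, 0, extra_noise_sigma)
    dy <- rnorm(n, 0, extra_noise_sigma)
    burst <- runif(n) < burst_prob
    nb <- sum(burst)
    if (nb > 0) {
      r <- runif(nb, 0, burst_max_m)
      theta <- runif(nb, 0, 2 * pi)
      dx[burst] <- dx[burst] + r * sin(theta)
      dy[burst] <- dy[burst] + r * cos(theta)
    }
    off <- offset_deg(study$gps$lat, dx, dy)
    study$gps$lat <- study$gps$lat + off$dlat
    study$gps$lon <- study$gps$lon + off$dlon
  })
  study
}

#' Write a synthetic study to the CSV dialects the readers expect
#'
#' Emits `gps.csv`, `accel.csv` and `diary.csv` under `dest`, in the
#' default column dialects of [read_gps_records()], [read_accel_records()]
#' and [read_diary()].
#'
#' @param study A `synthetic_study`.
#' @param dest Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_study_csv <- function(study, dest) {
  if (!dir.exists(dest)) dir.create(dest, recursive = TRUE)
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  gps_path <- file.path(dest, "gps.csv")
  readr::write_csv(
    tibble(timestamp = fmt(study$gps$timestamp),
           lat = study$gps$lat, lon = study$gps$lon),
    gps_path, progress = FALSE
  )
  accel_path <- file.path(dest, "accel.csv")
  readr::write_csv(
    tibble(timestamp = fmt(study$accel$timestamp),
           acc_x = study$accel$ax, acc_y = study$accel$ay,
           acc_z = study$accel$az),
    accel_path, progress = FALSE
  )
  diary_path <- file.path(dest, "diary.csv")
  readr::write_csv(
    tibble(begin = fmt(study$diary$begin), end = fmt(study$diary$end),
           lat = study$diary$lat, lon = study$diary$lon,
           address = study$diary$address),
    diary_path, progress = FALSE
  )
  invisible(c(gps = gps_path, accel = accel_path, diary = diary_path))
}
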