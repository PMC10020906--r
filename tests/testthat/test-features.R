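make_stops <- function(x_m, y_m, t0 = UTC0, dur = 3600, gap = 600) {
  ll <- ll_at(x_m, y_m)
  n <- length(x_m)
  starts <- t0 + (dur + gap) * (seq_len(n) - 1)
  tibble::tibble(
    stop_id = seq_len(n), start = starts, end = starts + dur,
    duration_s = dur, centroid_lat = ll$lat, centroid_lon = ll$lon,
    member_count = 10L, segment = 1L
  )
}

test_that("greedy location clustering matches a brute-force replay", {
  same <- cluster_locations(make_stops(c(0, 1, 2), c(0, 1, 0)))
  expect_equal(nrow(same), 1)
  expect_equal(same$visit_count, 3L)

  apart <- cluster_locations(make_stops(c(0, 500), c(0, 0)))
  expect_equal(nrow(apart), 2)

  # chain A-B-C 80 m apart plus random stops: replay the greedy rule
  set.seed(301)
  x <- c(0, 80, 160, runif(12, -400, 400))
  y <- c(0, 0, 0, runif(12, -400, 400))
  stops <- make_stops(x, y, dur = 1800, gap = 300)
  clusters <- cluster_locations(stops, radius_m = 100)
  got <- attr(clusters, "assignment")

  # independent oracle: literal sequential replay with dwell-weighted means
  centers <- list(); dwell <- c(); want <- integer(nrow(stops))
  for (i in seq_len(nrow(stops))) {
    p <- c(stops$centroid_lat[i], stops$centroid_lon[i])
    hit <- 0
    for (k in seq_along(centers)) {
      if (haversine_m(centers[[k]][1], centers[[k]][2], p[1], p[2]) <= 100) {
        hit <- k; break
      }
    }
    if (hit == 0) {
      centers[[length(centers) + 1]] <- p
      dwell <- c(dwell, stops$duration_s[i])
      want[i] <- length(centers)
    } else {
      tot <- dwell[hit] + stops$duration_s[i]
      centers[[hit]] <- (centers[[hit]] * dwell[hit] + p * stops$duration_s[i]) / tot
      dwell[hit] <- tot
      want[i] <- hit
    }
  }
  expect_equal(got, want)
  expect_equal(clusters$total_dwell_s, unname(dwell))
})

test_that("home detection prefers night dwell, with overrides", {
  single <- make_stops(0, 0)
  cl1 <- cluster_locations(single)
  expect_equal(detect_home(cl1, single), 1L)

  # A dwelled overnight, B only by day: A is home despite shorter dwell
  night <- as.POSIXct("2022-03-01 01:00:00", tz = "UTC")
  day <- as.POSIXct("2022-03-01 12:00:00", tz = "UTC")
  stops <- dplyr::bind_rows(
    make_stops(0, 0, t0 = night, dur = 2 * 3600),
    make_stops(1000, 0, t0 = day, dur = 8 * 3600)
  )
  stops$stop_id <- 1:2
  cl <- cluster_locations(stops)
  expect_equal(detect_home(cl, stops), 1L)

  # configured coordinates override the dwell heuristic
  b <- ll_at(1000, 0)
  expect_equal(detect_home(cl, stops, home_coords = c(b$lat, b$lon)), 2L)
  expect_warning(
    far <- detect_home(cl, stops, home_coords = c(48.9, 11)),
    "home"
  )
  expect_true(is.na(far))

  # no night dwell anywhere: fall back to max total dwell with a warning
  expect_warning(
    fb <- detect_home(cluster_locations(make_stops(c(0, 800), c(0, 0),
                                                   t0 = day, dur = 3600)),
                      make_stops(c(0, 800), c(0, 0), t0 = day, dur = 3600)),
    "night"
  )
  expect_equal(fb, 1L)
})

test_that("mode split thresholds on median leg speed with foot_bike ties", {
  trips <- tibble::tibble(
    trip_id = 1:4, start = UTC0, end = UTC0 + 600, duration_s = 600,
    length_m = 1000, median_speed_kmh = c(4, 50, 20, NA),
    n_fixes = c(10L, 10L, 10L, 1L), segment = 1L, path = list(NULL)
  )
  expect_warning(out <- mode_split(trips), "single fix")
  expect_equal(out$mode, c("foot_bike", "vehicle", "foot_bike", "foot_bike"))
})

test_that("revisited paths use unordered endpoint pairs", {
  # stops A, B, A, C, with trips abutting them exactly
  mk <- function(xs, t0) {
    st <- make_stops(xs, rep(0, length(xs)), t0 = t0, dur = 1800, gap = 600)
    st$stop_id <- seq_len(nrow(st))
    st
  }
  stops <- mk(c(0, 500, 0, 1500), UTC0)
  trips <- tibble::tibble(
    trip_id = 1:3,
    start = stops$end[1:3], end = stops$start[2:4],
    duration_s = 600, length_m = 500, median_speed_kmh = 5,
    n_fixes = 10L, segment = 1L, path = list(NULL)
  )
  cl <- cluster_locations(stops)
  # A->B, B->A, A->C: the unordered pair {A,B} recurs -> 2 of 3 revisited
  expect_equal(revisited_paths_pct(trips, stops, cl), 100 * 2 / 3)

  # all-distinct pairs -> 0
  stops2 <- mk(c(0, 500, 1500, 3000), UTC0)
  trips2 <- dplyr::mutate(trips, start = stops2$end[1:3], end = stops2$start[2:4])
  expect_equal(revisited_paths_pct(trips2, stops2, cluster_locations(stops2)), 0)

  # A->B then B->A only: unordered key makes both revisited
  stops3 <- mk(c(0, 500, 0), UTC0)
  trips3 <- trips[1:2, ]
  trips3$start <- stops3$end[1:2]; trips3$end <- stops3$start[2:3]
  expect_equal(revisited_paths_pct(trips3, stops3, cluster_locations(stops3)), 100)
})

test_that("a constructed excursion day yields the expected daily features", {
  # home dwell 2 h, 30 min walk out, 2 h visit 3 km away, 30 min walk back,
  # home dwell 2 h; fixes every 10 s, noise-free
  leg <- function(t0, t1, x0, x1) {
    tt <- seq(t0, t1 - 10, by = 10)
    list(t = tt, x = x0 + (tt - t0) / (t1 - t0) * (x1 - x0))
  }
  parts <- list(
    leg(0, 7200, 0, 0), leg(7200, 9000, 0, 3000), leg(9000, 16200, 3000, 3000),
    leg(16200, 18000, 3000, 0), leg(18000, 25200, 0, 0)
  )
  tt <- unlist(lapply(parts, `[[`, "t"))
  xx <- unlist(lapply(parts, `[[`, "x"))
  gps <- make_gps(xx, rep(0, length(xx)), dt = 1)
  gps$timestamp <- UTC0 + tt
  fit <- run_stop_go(gps, NULL, classifier_params(use_motion = FALSE))
  expect_equal(nrow(fit$stops), 3)

  daily <- daily_features(fit$samples, fit$stops, fit$trips)
  expect_equal(nrow(daily), 1)
  expect_gte(daily$max_distance_from_home_m, 2990)
  # out of home = visit + both walks = 3 h, within classifier boundary slack
  expect_equal(daily$time_out_of_home_s, 3 * 3600, tolerance = 0.02)
  expect_equal(daily$n_locations, 3L)
  expect_equal(daily$n_unique_locations, 2L)
  expect_equal(daily$time_most_moved, "morning") # both trips before 11:00 UTC
  expect_equal(as.numeric(daily$first_move_time) - as.numeric(UTC0), 7200,
               tolerance = 200)
  # dwell split ~ (4 h home, 2 h visit): entropy of (2/3, 1/3)
  expect_equal(daily$location_entropy,
               -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3)), tolerance = 0.02)
})

test_that("daily features satisfy accounting and geometry invariants", {
  st <- simulate_study(sim_config(seed = 21, n_days = 3))
  fit <- run_stop_go(st$gps, st$accel)
  daily <- daily_features(fit$samples, fit$stops, fit$trips)
  expect_equal(nrow(daily), 3)
  for (i in seq_len(nrow(daily))) {
    covered <- daily$time_at_home_s[i] + daily$time_out_of_home_s[i]
    expect_equal(covered, 12 * 3600, tolerance = 1e-6) # recording window
    expect_lte(daily$n_unique_locations[i], daily$n_locations[i])
    expect_gte(daily$revisited_life_space_pct[i], 0)
    expect_lte(daily$revisited_life_space_pct[i], 100)
    expect_lte(daily$location_entropy[i],
               log(daily$n_unique_locations[i]) + 1e-9)
    expect_gte(daily$hull_area_m2[i], 0)
    # mode time budgets partition the day's trip time
    expect_lte(daily$time_foot_bike_s[i] + daily$time_vehicle_s[i],
               daily$time_out_of_home_s[i] + 1e-6)
  }
  # every day's fixes lie inside that day's hull (point-in-polygon)
  dates <- lubridate::as_date(fit$samples$timestamp)
  for (d in unique(dates)) {
    pts <- fit$samples[dates == d, ]
    xy <- project_local(pts$lat, pts$lon)
    hull <- grDevices::chull(xy$x, xy$y)
    hx <- xy$x[hull]; hy <- xy$y[hull]
    if (sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy) < 0) {
      hx <- rev(hx); hy <- rev(hy) # enforce counter-clockwise
    }
    n <- length(hx)
    inside <- rep(TRUE, nrow(xy))
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1 else k + 1
      cross <- (hx[k2] - hx[k]) * (xy$y - hy[k]) -
        (hy[k2] - hy[k]) * (xy$x - hx[k])
      inside <- inside & (cross >= -1e-6)
    }
    expect_true(all(inside))
  }
})
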