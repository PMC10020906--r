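test_that("canonical dwell and canonical movement are labeled correctly", {
  # 12 fixes over 11 minutes, all within a few metres: one dwell
  dwell <- make_gps(rep(c(-2, 2), 6), rep(c(1, -1), 6), dt = 60)
  lab <- classify_samples(dwell)
  expect_true(all(lab$label == "stop"))

  # 80 m advance every 10 s (~29 km/h): all movement
  run <- make_gps(seq(0, 80 * 40, by = 80), rep(0, 41), dt = 10)
  expect_true(all(classify_samples(run)$label == "trip"))

  # a 4-minute stationary cluster between two movements is below the
  # strict >5 min rule: everything stays a trip
  x <- c(seq(-400, -80, by = 80), rep(0, 25), seq(80, 400, by = 80))
  clus <- make_gps(x, rep(0, length(x)), dt = 10)
  expect_true(all(classify_samples(clus)$label == "trip"))

  # degenerate inputs
  one <- make_gps(0, 0)
  expect_equal(classify_samples(one)$label, "stop")
  expect_equal(nrow(classify_samples(one[0, ])), 0)
})

test_that("motion score bridges a GPS-noise excursion, spatial mode splits it", {
  # 10 min dwell, 90 s excursion 150 m away, 10 min dwell; device at rest
  x <- c(rep(0, 61), rep(150, 9), rep(0, 61))
  t_off <- c(seq(0, 600, by = 10), seq(610, 690, by = 10), seq(700, 1300, by = 10))
  gps <- make_gps(x, rep(0, length(x)), dt = 1)
  gps$timestamp <- UTC0 + t_off
  accel <- make_accel(rep(9.81, 1301))
  params_m <- classifier_params(merge_gap_s = 60, use_motion = TRUE)
  params_s <- classifier_params(merge_gap_s = 60, use_motion = FALSE)

  with_motion <- run_stop_go(gps, accel, params_m)
  expect_equal(nrow(with_motion$stops), 1)
  expect_equal(with_motion$stops$duration_s, 1300)
  # centroid from non-bridged members only: unaffected by the excursion
  expect_equal(haversine_m(with_motion$stops$centroid_lat,
                           with_motion$stops$centroid_lon,
                           gps$lat[1], gps$lon[1]), 0, tolerance = 0.5)

  without <- run_stop_go(gps, NULL, params_s)
  expect_equal(nrow(without$stops), 2)
  expect_equal(nrow(without$trips), 1)
})

test_that("aggregation merges, relabels short stops and conserves time", {
  # hand-built label runs: stop (360 s), trip, stop (360 s)
  x <- c(rep(0, 4), seq(100, 400, by = 100), rep(500, 4))
  gps <- make_gps(x, rep(0, 12), dt = 120)
  gps$label <- rep(c("stop", "trip", "stop"), each = 4)
  gps$segment <- 1L
  gps$bridged <- FALSE
  iv <- aggregate_intervals(gps, classifier_params())
  expect_equal(nrow(iv$stops), 2)
  expect_equal(nrow(iv$trips), 1)
  expect_equal(sum(iv$stops$duration_s) + sum(iv$trips$duration_s),
               as.numeric(gps$timestamp[12]) - as.numeric(gps$timestamp[1]))

  # two stops 60 s apart with near-identical centroids merge (gap < 120 s)
  x2 <- c(rep(0, 7), 200, rep(10, 7))
  t2 <- c(seq(0, 360, by = 60), 390, seq(420, 780, by = 60))
  gps2 <- make_gps(x2, rep(0, 15), dt = 1)
  gps2$timestamp <- UTC0 + t2
  gps2$label <- c(rep("stop", 7), "trip", rep("stop", 7))
  gps2$segment <- 1L
  gps2$bridged <- FALSE
  iv2 <- aggregate_intervals(gps2, classifier_params())
  expect_equal(nrow(iv2$stops), 1)
  expect_equal(iv2$stops$duration_s, 780)

  expect_error(aggregate_intervals(make_gps(0, 0), classifier_params()),
               class = "mobitrace_contract_error")
})

test_that("adding stationary samples inside a stop never splits it", {
  gps <- make_gps(rep(0, 61), rep(0, 61), dt = 10)
  base <- run_stop_go(gps, NULL, classifier_params(use_motion = FALSE))
  expect_equal(nrow(base$stops), 1)
  extra <- make_gps(rep(0, 30), rep(0, 30), dt = 10)
  extra$timestamp <- UTC0 + 5 + 10 * (0:29)
  denser <- dplyr::arrange(dplyr::bind_rows(gps, extra), timestamp)
  fit <- run_stop_go(denser, NULL, classifier_params(use_motion = FALSE))
  expect_equal(nrow(fit$stops), 1)
  expect_equal(as.numeric(fit$stops$start), as.numeric(base$stops$start))
  expect_equal(as.numeric(fit$stops$end), as.numeric(base$stops$end))
})

test_that("stops and trips tile each recording segment on simulated days", {
  for (seed in 1:3) {
    st <- simulate_study(sim_config(seed = seed, n_days = 1))
    fit <- run_stop_go(st$gps, st$accel)
    expect_tiling(fit)
    # every stop is a genuine dwell: strict duration and radius containment
    expect_true(all(fit$stops$duration_s > 300))
    t <- as.numeric(fit$samples$timestamp)
    for (i in seq_len(nrow(fit$stops))) {
      m <- fit$samples[t >= as.numeric(fit$stops$start[i]) &
                         t <= as.numeric(fit$stops$end[i]) &
                         fit$samples$label == "stop" &
                         !fit$samples$bridged, ]
      d <- haversine_m(m$lat, m$lon,
                       fit$stops$centroid_lat[i], fit$stops$centroid_lon[i])
      expect_lte(max(d), 100 + 1e-6)
    }
    expect_true(!is.unsorted(as.numeric(fit$stops$start)))
  }
})

test_that("noise-free simulations are recovered to within one sample", {
  for (seed in c(5, 11)) {
    st <- simulate_study(sim_config(seed = seed, n_days = 1,
                                    gps_noise_sigma = 0, dropout_prob = 0))
    fit <- run_stop_go(st$gps, st$accel)
    expect_equal(nrow(fit$stops), nrow(st$diary))
    expect_true(all(abs(as.numeric(fit$stops$start) -
                          as.numeric(st$diary$begin)) <= 10 + 1e-9))
    expect_true(all(abs(as.numeric(fit$stops$end) -
                          as.numeric(st$diary$end)) <= 10 + 1e-9))
    expect_gte(mean(fit$samples$label == st$gps$truth), 0.999)

    # motion is corrective only: identical result without it on clean data
    fit_nm <- run_stop_go(st$gps, NULL,
                          classifier_params(use_motion = FALSE))
    expect_equal(tidy(fit_nm), tidy(fit))
  }
})

test_that("missing accelerometer data reduces to the spatial classifier", {
  st <- simulate_study(sim_config(seed = 9, n_days = 1))
  with_empty <- run_stop_go(st$gps, st$accel[0, ],
                            classifier_params(use_motion = TRUE))
  spatial <- run_stop_go(st$gps, NULL, classifier_params(use_motion = FALSE))
  expect_equal(tidy(with_empty), tidy(spatial))
})

test_that("classifier parameters are validated", {
  expect_error(classifier_params(min_stop_s = 0), class = "mobitrace_param_error")
  expect_error(classifier_params(stop_radius_m = -5), class = "mobitrace_param_error")
  expect_error(classifier_params(merge_gap_s = -1), class = "mobitrace_param_error")
})
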