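mk_diary <- function(begins, ends, x = 0, y = 0) {
  ll <- ll_at(rep(x, length(begins))[1], rep(y, length(begins))[1])
  tibble::tibble(
    begin = UTC0 + begins, end = UTC0 + ends,
    lat = ll$lat, lon = ll$lon, address = NA_character_
  )
}

test_that("ground-truth labeling uses closed diary intervals", {
  diary <- mk_diary(c(0, 1200), c(600, 1800))
  gps <- make_gps(rep(0, 5), rep(0, 5), dt = 1)
  gps$timestamp <- UTC0 + c(300, 900, 1200, 600, 86400 * 3)
  out <- ground_truth_labels(gps, diary)
  expect_equal(out$truth[1], "stop")  # midpoint of a stop
  expect_equal(out$truth[2], "trip")  # between two stops
  expect_equal(out$truth[3], "stop")  # exactly at a begin instant
  expect_equal(out$truth[4], "stop")  # exactly at an end instant
  expect_true(is.na(out$truth[5]))    # day not covered by the diary
})

test_that("sample metrics match formulas, oracles and published arithmetic", {
  perfect <- rep(c("stop", "trip"), 50)
  m <- sample_metrics(perfect, perfect)
  expect_equal(m$percent_correct, 100)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$f1, 1)

  # a field data set with 119,614 of 122,808 samples agreeing is 97.40%
  n_total <- 122808L
  n_agree <- 119614L
  pred <- rep("stop", n_total)
  truth <- c(rep("stop", n_agree), rep("trip", n_total - n_agree))
  expect_equal(round(sample_metrics(pred, truth)$percent_correct, 2), 97.40)

  # random labels against a brute-force confusion tally
  set.seed(401)
  p <- sample(c("stop", "trip"), 200, replace = TRUE)
  t <- sample(c("stop", "trip"), 200, replace = TRUE)
  m2 <- sample_metrics(p, t)
  tp <- sum(p == "stop" & t == "stop"); tn <- sum(p == "trip" & t == "trip")
  fp <- sum(p == "stop" & t == "trip"); fn <- sum(p == "trip" & t == "stop")
  expect_equal(c(m2$tp, m2$tn, m2$fp, m2$fn), c(tp, tn, fp, fn))
  expect_equal(m2$n, 200L)
  expect_equal(m2$percent_correct, 100 * (tp + tn) / 200)
  expect_equal(m2$balanced_accuracy, (tp / (tp + fn) + tn / (tn + fp)) / 2)
  expect_equal(m2$f1, 2 * tp / (2 * tp + fp + fn))
  expect_true(m2$balanced_accuracy >= 0 && m2$balanced_accuracy <= 1)

  # zero denominators give missing metrics, not zero
  all_stop <- sample_metrics(rep("stop", 10), rep("stop", 10))
  expect_true(is.na(all_stop$balanced_accuracy))
  expect_equal(all_stop$f1, 1)
  expect_error(sample_metrics(c("stop"), c("stop", "trip")),
               class = "mobitrace_contract_error")
})

test_that("interval matching classifies correct, missed and fragmented stops", {
  mk_stops <- function(begins, ends) {
    ll <- ll_at(0, 0)
    tibble::tibble(
      stop_id = seq_along(begins), start = UTC0 + begins, end = UTC0 + ends,
      duration_s = ends - begins, centroid_lat = ll$lat, centroid_lon = ll$lon,
      member_count = 5L, segment = 1L
    )
  }
  no_trips <- mk_stops(numeric(0), numeric(0))

  diary <- mk_diary(c(0, 7200), c(3600, 10800))
  # exact match of diary stop 1; stop 2 untouched
  r1 <- match_intervals(mk_stops(0, 3600), no_trips, diary)
  expect_equal(r1$correct_stops, 1L)
  expect_equal(r1$missed_stops, 1L)
  expect_equal(r1$fragmented_stops, 0L)
  expect_equal(r1$diary_trips, 1L)
  expect_equal(r1$missed_trips, 1L)

  # two detected stops inside one diary stop: fragmented, both correct
  r2 <- match_intervals(mk_stops(c(0, 2000), c(1500, 3600)), no_trips, diary)
  expect_equal(r2$fragmented_stops, 1L)
  expect_equal(r2$correct_stops, 2L)

  # disjoint detection: diary stop missed
  r3 <- match_intervals(mk_stops(4000, 5000), no_trips, diary)
  expect_equal(r3$missed_stops, 2L)
  expect_equal(r3$correct_stops, 0L)

  # a sliver overlap is an overlap (not missed) but fails the 50% rule
  r4 <- match_intervals(mk_stops(3500, 7300), no_trips, diary)
  expect_equal(r4$missed_stops, 0L)
  expect_equal(r4$correct_stops, 0L)

  # empty diary
  r5 <- match_intervals(mk_stops(0, 3600), no_trips, mk_diary(numeric(0), numeric(0)))
  expect_equal(r5$diary_stops, 0L)
  expect_equal(r5$missed_stops, 0L)
})

test_that("each diary stop falls in exactly one accounting category", {
  set.seed(402)
  for (rep_i in 1:5) {
    n <- 6
    begins <- sort(runif(n, 0, 40000))
    ends <- begins + runif(n, 400, 3000)
    begins[-1] <- pmax(begins[-1], ends[-n] + 60) # enforce separation
    ends <- pmax(ends, begins + 400)
    diary <- mk_diary(begins, ends)
    # jittered detections: some shifted, some split, some dropped
    det_b <- c(); det_e <- c()
    for (i in seq_len(n)) {
      u <- runif(1)
      if (u < 0.2) next # dropped -> missed
      if (u < 0.5) {    # split in two -> fragmented
        mid <- (begins[i] + ends[i]) / 2
        det_b <- c(det_b, begins[i], mid + 30)
        det_e <- c(det_e, mid - 30, ends[i])
      } else {
        det_b <- c(det_b, begins[i] + 30)
        det_e <- c(det_e, ends[i] - 30)
      }
    }
    ll <- ll_at(0, 0)
    det <- tibble::tibble(
      stop_id = seq_along(det_b), start = UTC0 + det_b, end = UTC0 + det_e,
      duration_s = det_e - det_b, centroid_lat = ll$lat,
      centroid_lon = ll$lon, member_count = 2L, segment = 1L
    )
    r <- match_intervals(det, det[0, ], diary)
    singly <- r$diary_stops - r$missed_stops - r$fragmented_stops
    expect_gte(singly, 0)
    expect_equal(r$missed_stops + r$fragmented_stops + singly, r$diary_stops)
  }
})

test_that("benchmark report saturates on clean data and is deterministic", {
  st <- simulate_study(sim_config(seed = 31, n_days = 1,
                                  gps_noise_sigma = 0, dropout_prob = 0))
  ev <- benchmark_report(st$gps, st$accel, st$diary)
  expect_s3_class(ev, "stop_go_eval")
  expect_equal(ev$with_motion$intervals$missed_stops, 0L)
  expect_equal(ev$with_motion$intervals$fragmented_stops, 0L)
  expect_equal(ev$with_motion$intervals$correct_stops,
               ev$with_motion$intervals$detected_stops)
  # clean GPS: both configurations identical
  expect_equal(ev$comparison$with_motion, ev$comparison$without_motion)

  ev2 <- benchmark_report(st$gps, st$accel, st$diary)
  expect_identical(tidy(ev), tidy(ev2))
  expect_equal(nrow(glance(ev)), 1)
})
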