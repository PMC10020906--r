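# mobitrace

Smartphone GPS recordings are increasingly used to quantify the *life
space* of older adults and clinical populations: how far from home a
person ranges, how many distinct places they visit, how much time they
spend out of the house and in transit. Every such analysis stands on one
foundational step — splitting the raw fix stream into **stops** (more than
5 minutes spent within a 100 m radius) and **trips** (movement between
stops). `mobitrace` implements that step and everything around it as a
tidyverse-native R package:

- **Ingest** — CSV readers for GPS fixes (~0.1 Hz), 3-axis accelerometer
  samples (1 Hz) and stop diaries, with configurable column maps,
  UTC-normalised timestamp auto-detection, study-window trimming and GPX
  1.1 export.
- **Preprocessing** — duplicate removal and a per-epoch **motion score**:
  the population standard deviation of the acceleration-vector magnitude
  √(ax² + ay² + az²) per 30 s epoch, zero for a device at rest and
  invariant under device rotation.
- **Stop & Go classification** — stay-point detection with a running
  centroid (stop iff a maximal run of fixes stays within `stop_radius_m`
  of its running centroid for more than `min_stop_s`), boundary
  refinement, gap/radius merging, and motion-score fusion that bridges
  GPS-noise excursions when the accelerometer shows the device was
  physically still — suppressing *fragmented stops*, the classic failure
  mode where one true dwell is reported as several short ones.
- **Mobility variables** — per participant-day: maximum/average distance
  from home, convex-hull area/perimeter/compactness (4πA/P²), robust
  standard-ellipse area (deterministic minimum-covariance-determinant
  scatter), 200 m-buffered **daily path area**, revisited life space %,
  location counts and clusters, time at/out of home, foot-bike vs vehicle
  time split (median leg speed threshold), first-move time, most-active
  time of day, revisited-path % and location entropy
  H = −Σ pᵢ ln pᵢ over dwell-time shares.
- **Evaluation** — per-sample confusion metrics (percent correct,
  balanced accuracy, F1) and interval-level matching against a diary
  ground truth (correct / missed / fragmented stops, missed trips), with
  a side-by-side with/without-motion-score report.
- **Simulation** — a seeded generator of complete synthetic studies
  (schedule, GPS noise, dropout, accelerometer regimes, diary ground
  truth) plus a degradation operator (extra noise, heavy-tailed position
  bursts), so the whole pipeline is testable without any field data.

## Worked example

```r
library(mobitrace)

study <- simulate_study(sim_config(seed = 42, n_days = 3))
study
#> Synthetic mobility study (seed 42)
#>   days  : 3
#>   fixes : 12686  accel samples: 129603
#>   diary : 11 stops

fit <- run_stop_go(study$gps, study$accel)
fit
#> Stop & Go segmentation
#>   samples : 12686
#>   stops   : 11
#>   trips   : 8
#>   median stop duration: 52.5 min

head(tidy(fit), 3)
#> # A tibble: 3 x 13
#>   type  stop_id start               end                 duration_s ...
#> 1 stop        1 2022-03-01 08:00:00 2022-03-01 08:33:10       1990
#> 2 trip       NA 2022-03-01 08:33:10 2022-03-01 08:37:00        230
#> 3 stop        2 2022-03-01 08:37:00 2022-03-01 09:29:30       3150
```

The 11 diary dwells are recovered as 11 stops; stops and trips abut, so
each day's intervals tile the 12-hour recording window exactly. Daily
mobility variables and the diary evaluation follow the same
data-frame-in, tibble-out style:

```r
daily <- daily_features(fit$samples, fit$stops, fit$trips)
dplyr::select(daily, date, n_locations, time_out_of_home_s, hull_area_m2,
              location_entropy)
#> # A tibble: 3 x 5
#>   date       n_locations time_out_of_home_s hull_area_m2 location_entropy
#> 1 2022-03-01           3               3890       52424.            0.264
#> 2 2022-03-02           4               7900      747907.            0.549
#> 3 2022-03-03           4               7140      578494.            0.476

glance(benchmark_report(study$gps, study$accel, study$diary))
#> # A tibble: 1 x 16
#>      tp    tn    fp    fn     n percent_correct balanced_accuracy    f1 ...
#> 1 12405   257    24     0 12686            99.8             0.957 0.999
```

Here `time_out_of_home_s` is the day's trip time plus non-home dwell
time, `location_entropy` the Shannon entropy (nats) of dwell time over
distinct locations, and the last line the classifier's per-sample
accuracy against the simulator's diary: 99.8% of samples correctly
labeled, F1 = 0.999 at 10 m GPS noise.

A command-line interface wraps the same functions
(`inst/cli/mobitrace.R`; subcommands `simulate`, `classify`, `features`,
`evaluate`, `run`, configured by a YAML file).

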