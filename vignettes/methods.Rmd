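---
title: "Methods: stop/trip segmentation and life-space metrics in mobitrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stop/trip segmentation and life-space metrics in mobitrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mobitrace` turns raw smartphone sensor streams — GPS fixes at roughly
one per 10 seconds and 3-axis accelerometer samples at 1 Hz — into the
stop/trip segmentation and the daily life-space variables that mobility
studies of older adults are built on. This vignette documents the model,
its tunable parameters, the numerical choices, and what the synthetic
study generator does and does not emulate.

## The segmentation model

A **stop** is a period of more than `min_stop_s` seconds (default 300;
the bound is strict, so a dwell of exactly five minutes is not a stop)
spent within a circle of `stop_radius_m` metres (default 100). Everything
between stops is a **trip**. Detection uses stay-point detection with a
running centroid: scanning forward from a candidate anchor fix, fixes are
absorbed while each next fix lies within the stop radius of the running
mean position of the fixes absorbed so far; if the absorbed run spans
more than the minimum duration it is a stop run, otherwise the anchor
advances one fix. The running-centroid rule tolerates GPS scatter around
a dwell without letting slow drift (walking) masquerade as a stop.

Three post-processing rules shape the final intervals:

1. **Boundary refinement.** A departure drags the first ~radius metres of
   walking into the candidate run (fixes stay within 100 m of the
   centroid while the person walks away). Members are therefore peeled
   off both ends of a run while they lie farther from the run centroid
   than 3.5× the median member distance (capped at the stop radius), with
   the centroid recomputed after each peel. The multiplier sits well
   above the Rayleigh scatter of stationary fixes, so genuine dwell
   members are never peeled; on noise-free data the rule recovers the
   true boundary to within one sampling period.
2. **Motion-gated fragment suppression.** When accelerometry is
   available, trip-labeled fixes caught between two stop runs whose
   centroids are within the stop radius are relabeled stop if their
   motion score is at or below the motion threshold: a physically still
   device that suffered a GPS-noise excursion stays in one stop instead
   of fragmenting into several. Fixes whose score exceeds the threshold
   are evidence of genuine movement and are never bridged; fixes with no
   accelerometer coverage are never bridged either, so the classifier
   degrades gracefully to its purely spatial form. Bridged fixes are
   flagged and excluded from stop centroids, which are means over the
   spatially conforming members only.
3. **Aggregation.** Maximal constant-label runs become intervals; stop
   runs that no longer exceed the minimum duration are relabeled trip;
   consecutive stops separated by a gap shorter than `merge_gap_s`
   (default 120 s) with centroids within the stop radius merge into one.
   Interval boundaries abut — an interval ends where the next starts — so
   stops and trips tile the covered recording time exactly. Recording
   gaps longer than `gap_split_s` (default 1800 s; phones are charged or
   off overnight) split the record into segments and no interval spans
   them. Sample labels use half-open membership `[start, end)` at
   interior boundaries (the segment's last interval is closed), so the
   first moving fix after a dwell belongs to the trip.

### The motion score and its threshold

The motion score of an epoch (default `epoch_s = 30`) is the population
standard deviation of the acceleration-vector magnitude
$\sqrt{a_x^2+a_y^2+a_z^2}$ over the epoch's samples. Using the magnitude
makes the score invariant under any fixed device rotation; using the
standard deviation makes it zero at rest, where gravity contributes only
a constant offset. Population (not sample) variance keeps two-sample
epochs deterministic; epochs with fewer than two samples score zero. The
score is deliberately unnormalised — its units are device units — so the
classification threshold must live in the same units.

The default threshold is data-adaptive: **4× the 25th percentile of the
positive epoch scores**, capped at the geometric midpoint between that
percentile and the maximum score. The reasoning: day-long life-space
recordings are dwell-dominated, so low quantiles of the score
distribution estimate the at-rest score level; at 30 s epochs the rest
score has roughly 13% relative scatter, so a factor of four clears it
with a wide margin while remaining far below carried-movement scores,
which are an order of magnitude larger. A bare low quantile would sit
*inside* the rest scatter — about half of genuinely still epochs would
exceed it and fragment suppression would rarely fire — and symmetric
"midpoint between score clusters" rules fail because movement epochs are
only a few percent of a day, leaving every moderate quantile at rest
level. The cap protects the rare movement-heavy record. The threshold is
a single number and can always be set explicitly
(`classifier_params(motion_threshold = ...)`).

## Life-space geometry

All planar geometry runs in a local azimuthal-equidistant projection
centred on the point cloud: a point maps to $(d\sin\beta, d\cos\beta)$
with $d$ its great-circle distance (haversine, sphere radius
6,371,008.8 m) from the centre and $\beta$ the spherical initial bearing.
Distance and bearing use the same spherical model, so projecting and
unprojecting are exact inverses; distortion at daily-mobility extents
(tens of kilometres) is negligible.

- **Convex hull** metrics (area, perimeter, Polsby–Popper compactness
  $4\pi A/P^2$, which is 1 for a circle) use the planar hull of the day's
  fixes. A hull whose area is numerically zero relative to its perimeter
  (collinear clouds) is treated as degenerate: area 0, compactness
  missing. Compactness is bounded in (0, 1], which is why the
  Polsby–Popper form was chosen among the possible compactness indices.
- **Robust standard ellipse.** Location and scatter come from a
  deterministic minimum-covariance-determinant refinement — concentration
  steps from the classical estimate down to the half-sample with the
  smallest covariance determinant — followed by the standard reweighting
  step (classical covariance of the non-outlier points). Determinism
  matters twice: results are bit-reproducible, and every step is
  affine-equivariant, so the area is exactly invariant under rotations of
  the cloud, which stochastic subset search cannot guarantee. Outliers
  are points whose squared robust Mahalanobis distance exceeds 8× the
  median squared distance — a *scale-free* rule, chosen because absolute
  chi-squared cutoffs assume Gaussian calibration that real fix clouds do
  not satisfy. The reported area is $\pi s^2 \sqrt{\det\Sigma}$ with
  $s^2$ the largest squared robust distance among inliers: the smallest
  covariance-shaped ellipse containing all inliers. Any mis-scaling of
  $\Sigma$ cancels between $s^2$ and $\sqrt{\det\Sigma}$, so the estimate
  is self-calibrating and tracks the minimum-area covering ellipse of the
  inliers. Fewer than three distinct points, or a singular scatter, give
  area 0.
- **Daily path area** buffers each trip polyline by 200 m and returns the
  area of the dissolved union. With no exact polygon-clipping library on
  the dependency list, the union is evaluated numerically: paths are
  densified to at most buffer/20 vertex spacing (the sagitta error of
  approximating a capsule by discs at that spacing is below a decimetre),
  a distance field to the vertex set is rasterised at buffer/40 cell
  size, and boundary cells contribute their linear coverage fraction
  (antialiasing). The tests hold the result to within 1% of the capsule
  closed form 2·b·L + πb². Water-body removal is out of scope: the
  package has no GIS hydrology layer, so areas over water are included.
- **Revisited life space** intersects each day's hull with the union of
  all other days' hulls, exactly: convex–convex intersections via
  Sutherland–Hodgman clipping and the union area via inclusion–exclusion
  over the (convex) pairwise intersections, all in one shared projection.
  Days with degenerate hulls are reported missing and excluded from
  other days' unions.
- **Location entropy** is $H=-\sum_i p_i\ln p_i$ over the shares of dwell
  time per location cluster. The base is *e* (nats); no convention is
  universal and natural log keeps $H \le \ln k$ statements clean.

## Locations, home, and derived variables

Stops cluster into locations greedily in time order: a stop joins the
first existing cluster whose (dwell-weighted mean) centroid lies within
100 m, else founds a new cluster. Greedy sequential clustering is
order-dependent but deterministic, cheap, and matches how "a place"
accumulates dwell over a study. **Home** is the cluster with the most
dwell between 00:00 and 06:00 local time (ties broken by total dwell;
configured home coordinates override the heuristic; with no night-time
dwell anywhere the maximum total dwell is used, with a warning).

Per-day variables cut the study at local midnight of a configurable time
zone; intervals spanning midnight contribute their within-day overlap to
each day. Time out of home is the day's trip time plus non-home dwell
time, so time at home + time out of home equals the covered (non-gap)
recording time by construction. Trips are classed foot/bike vs vehicle
by median leg speed against a 20 km/h threshold (ties and single-fix
trips fall to foot/bike) — a deliberate simplification; proper mode
inference would need accelerometer gait features or map matching. A
location is *revisited* when its cluster is visited at least twice
across the whole study; a trip is *revisited* when the unordered pair of
its endpoint clusters occurs at least twice (trips at recording edges,
with no adjacent stop, are excluded from that percentage). First-move
time is the start of the day's first trip; the most-active time of day
is the arg-max of trip starts over morning [05–11), noon [11–17) and
evening [17–23) bins, earliest bin winning ties.

## Diary evaluation

The diary gives ground-truth stops as closed intervals; a GPS sample is
truth-stop iff its timestamp lies in some diary interval, and samples on
days the diary does not cover have no truth and are excluded from
per-sample metrics. Reported metrics are percent correct, balanced
accuracy (mean of sensitivity and specificity, stop positive) and F1;
any metric with a zero denominator is missing, never zero. At interval
level, a detected stop is *correct* when its overlap with some diary
stop reaches 50% of the shorter of the two durations (the threshold is a
package choice, configurable, since "similar interval" admits many
operationalisations); a diary stop is *missed* when nothing overlaps it
and *fragmented* when two or more detected stops overlap it, fragmented
taking precedence, so every diary stop falls in exactly one category.
Diary trips are the gaps between consecutive diary stops shorter than
4 h — longer gaps are recording pauses (overnight), not trips — and a
diary trip is missed when no detected trip overlaps it.

## The synthetic study generator

`simulate_study()` emulates the recording conditions the pipeline is
designed for: a small set of recurring locations (one home) 0.5–3 km
apart; each day, dwells of 10–90 minutes alternating with straight-line
trips at foot/bike (3–15 km/h) or vehicle (25–60 km/h) speeds, the last
trip returning home; GPS fixes every 10 s inside a 08:00–20:00 recording
window (phones charge at home overnight) with isotropic Gaussian
position noise of 10 m and 2% fix dropout; a 1 Hz accelerometer whose
magnitude scatter is 0.05 device units at rest and 0.8 in motion around
a 9.81 gravity offset. All randomness flows from one seed, so a study is
bit-reproducible. `degrade()` adds what urban canyons and rural edges
do to GPS: extra Gaussian noise and heavy-tailed position bursts
(uniform direction, up to 300 m), leaving the ground truth untouched.

What the generator does *not* emulate — and therefore what passing tests
do not certify on field data: road-network-constrained movement and
realistic turning paths, multipath error that is correlated in time and
space rather than independent, device-specific accelerometer noise
spectra, diary timing error (the simulated diary is exact), and
multi-participant heterogeneity. Results on the generator bound the
algorithmic behaviour (partition invariants, boundary recovery,
fragmentation suppression), not field accuracy.

## Problem sizes and numerical conventions

The test suite exercises, among smaller fixtures: 100 simulated study
days (ten 10-day studies) for the partition/conservation invariants,
ten 7-day studies at 10 m noise and 5% dropout for the per-sample F1
floor of 0.95, twenty degraded one-day replicates for the directional
fragmentation experiment, and point clouds of 400–1000 points for the
geometry oracles — sizes chosen to make the statistical assertions
stable while the whole suite stays fast enough to run routinely.
Other conventions: timestamps are parsed to UTC (ISO-8601 or epoch
seconds/milliseconds, auto-detected); study-window bounds given as dates
are closed full days; duplicate fixes collapse to their first
occurrence; all tie-breaks in the package (mode split at the threshold,
most-active bin, home detection) are deterministic and documented at the
function level.

## Known limitations

The classifier's exact agreement with any particular reference
implementation depends on free parameters (motion threshold, merge gap,
overlap criterion) that published descriptions rarely pin down; the
package therefore exposes them all. Mode split by median speed cannot
separate bicycles from slow vehicles. Daily path area includes water.
Greedy location clustering can split a place that straddles the radius
boundary depending on visit order. The evaluation's 50% overlap rule is
one of several defensible correctness definitions; sensitivity to it can
be probed directly via `match_intervals(..., overlap_frac = )`.
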