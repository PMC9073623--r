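---
title: "Methods: GPS trajectory mining of outdoor mobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPS trajectory mining of outdoor mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gpsmobility)
```

`gpsmobility` turns raw GPS fix streams from small clinical cohorts — the
motivating setting is community-dwelling people with Alzheimer's disease and
age-matched controls tracked for two weeks — into eight per-participant
outdoor-navigation variables, environmental exposure features around their
walking routes, and a three-step group-comparison analysis. This vignette
explains the models and procedures, the tunable parameters and why their
defaults are what they are, what the synthetic cohort generator does and
does not emulate, and the numerical choices that shape edge-case behaviour.

## The measurement model

A tracker worn by each participant reports a fix — timestamp, WGS84
latitude/longitude, speed in km/h — every 3 s or every 5 s (both occur in
practice because device firmware changed mid-study in the setting this
package targets). Two device behaviours matter for the analysis:

* **Recording gaps.** The device stops recording after 2 minutes without
  movement. Time at rest therefore appears as an absence of data, not as a
  run of stationary fixes, and "time spent moving" can be computed without
  ever observing long stationary stretches.
* **Position error.** The error SD is taken as 10 m. The 30 m home geofence
  and the "+30 m" terms added to buffer radii are 3 SD of this error.

## Preprocessing

Three stages, in the order cleaning → smoothing → classification:

1. **Day cleaning** (`clean_days()`): a local calendar day with no fix
   farther than `home_radius_m` (30 m) from the home centroid contains no
   outdoor navigation and is dropped. A participant with no surviving days
   (the faulty-tracker case) is excluded with a logged reason. Local days
   use the cohort time zone (`Europe/London` by default; the study setting
   is British).
2. **Spike smoothing** (`remove_spikes()`): scanning consecutive fixes, a
   fix farther from the last retained fix than `spike_vmax_kmh` × Δt is a
   sensor artifact and is removed; the scan resumes from the last retained
   fix, so runs of consecutive spikes are all removed. The 200 km/h default
   exceeds any plausible ground travel; the operation is idempotent.
3. **Mode classification** (`window_and_classify()`): fixes are tiled into
   windows of 3 fixes (9 s) at 3 s sampling or 2 fixes (10 s) at 5 s —
   windows of nearly equal duration across both firmware generations.
   A window is `stationary` if its mean speed is below 1 km/h; `by_foot` if
   mean < 7 km/h and max < 12 km/h; else `in_vehicle`. These thresholds are
   a reconstruction — the separation points between resting jitter, walking
   (~4.5 km/h, with fast walking below 7) and vehicle travel — and every
   one is configurable. Device speed is used when present (receiver Doppler
   speed is far less noisy than differenced positions); otherwise speed is
   recomputed from consecutive geodesic displacements. Windows never span a
   recording gap.

## Outing segmentation

An outing runs from the moment the trace leaves the 30 m home geofence to
its return, and must cover at least `min_outing_path_m` (100 m) of
cumulative path outside the geofence; shorter excursions (bin runs, garden
strolls, noise wobble) are discarded. Two refinements make the home-to-home
rule robust to realistic GPS error:

* **Minimum home dwell.** An at-home run closes an outing only if it lasts
  at least `min_home_dwell_s` (120 s), touches a recording gap or a trace
  end. A single fix flipped inside the fence mid-outing (or outside it
  mid-dwell) by position error therefore cannot split or extend an outing.
* **Gap closure with home evidence.** A recording gap ends the current
  outing only when a fix immediately adjacent to the gap (within 15 s on
  either side) is at home — the trace went quiet *while near home*. A gap
  without home evidence is in-outing signal loss (e.g. a mid-outing stop
  long enough for the device to sleep) and does not split the outing. The
  evidence window is deliberately tight: a wider one would reach back
  through a short outing to its departure fixes and split it at such stops.

Reported outing distances are anchored at the home centroid: the segment
from the centroid to the first fix of the outing (and symmetrically at the
end) is part of the journey, while the fixes inside the geofence belong to
the at-home dwell. The minimum-length filter, by contrast, uses only the
path outside the geofence, so position noise wandering near the fence gains
no free length. Without the anchoring, every outing would lose roughly two
geofence radii of length; with a naive anchored filter, sustained 3 SD
noise excursions could fabricate outings. A candidate must additionally
reach `min_outing_displacement_m` (60 m = geofence + 3 SD of position
error) from home: sustained error offsets can accumulate well over 100 m
of tangential noise path while never getting clear of the fence, and such
wander is at-home time, not an outing. Any genuine 100 m out-and-back
excursion reaches ~50 m of true displacement, so the floor costs no real
outings at the scales the pipeline targets.

Outings truncated by the trace start/end are kept (flagged `truncated`) if
they satisfy the length rule; discarding them would bias counts downward.

Day/night labels follow the outing's start clock time, daytime being the
inclusive band 06:00–18:00 (minute resolution: 18:00 is day, 18:01 is
night). An outing spanning 18:00 lands in the band of its start — a
deliberate choice, since each outing must be counted once.

Accompaniment labels come from a navigation diary: an outing inherits the
label of the nearest diary entry within ±30 minutes, each entry matching at
most one outing; unmatched outings are `unknown` and excluded from
alone/accompanied splits.

## The eight mobility variables

Per participant (and per accompaniment condition for patients):

* outings per day, day outings per day, night outings per day — counts over
  the days surviving day cleaning;
* time spent moving per outing (h) — the sampling-time contribution of
  fixes in non-stationary windows; recording gaps contribute nothing;
* total distance per outing (km) — home-anchored consecutive-fix path;
* walking distance per outing (km) — the same sum restricted to pairs of
  fixes in by-foot windows;
* mean distance from home per outing (km) — mean over the outing's fixes of
  geodesic distance to the home centroid;
* similarity of trajectories — the mean discrete Fréchet distance over all
  unordered pairs of outing trajectories.

The discrete Fréchet distance is computed by the standard dynamic program
over the coupling table, `c(i,j) = max(d(a_i,b_j), min(c(i-1,j),
c(i-1,j-1), c(i,j-1)))`, the minimum over monotone couplings of the maximum
coupled pair distance. Two conventions are provided because published mean
values of this metric are sometimes left in raw coordinate units:
`dfd_units = "meters"` (geodesic; the default, interpretable) and
`"degrees"` (Euclidean on raw coordinates). Trajectories are downsampled by
uniform stride to `dfd_max_points` (500) fixes before the quadratic table
is built; at 0.33 Hz an outing can carry thousands of fixes, and the stride
changes the distance by far less than the GPS noise floor. Inside
`trajectory_similarity()` the meters convention projects all trajectories
once into a shared local azimuthal-equidistant frame and uses Euclidean
distances — identical to the geodesic computation to ~10⁻⁶ relative at
outing scales and an order of magnitude faster across all pairs. Self-pairs
are excluded from "all combinations": they are identically zero and would
bias the mean toward similarity.

## Geospatial features

Only walking trajectories are buffered — disorientation while seated in a
vehicle is not at issue. Three buffer radii are used, each assembled from a
core radius plus a 30 m (3 SD) error term: 50 + 30 = 80 m for landmark
capture along a walked route, 30 m for road contact, and 2000 + 30 = 2030 m
for orientation entropy of the surrounding street network.

No geometry engine is assumed: buffers are built in a local
azimuthal-equidistant projection centred on the trajectory (distortion
below 0.1% at these radii), and the buffer polygon — the Minkowski dilation
of the polyline — is represented exactly as the union of per-segment
rectangles and per-vertex discs, against which membership is tested in
compiled code. Areas, when wanted, come from midpoint grid integration.

* **Landmark density** — landmarks inside the 80 m buffer per walking km.
* **Intersection density and complexity** — road-network nodes of degree
  ≥ 3 inside the 30 m buffer, per walking km; complexity is the node degree
  (the number of road legs), the only definition computable from a generic
  node/edge network.
* **Orientation entropy** — each road edge is clipped to the 2.03 km buffer
  by 10 m sub-segments; sub-segment lengths accumulate into 36 bins of 10°
  under both the edge bearing and its reverse (streets are undirected), and
  the Shannon entropy of the length-weighted distribution is reported in
  nats: ln 2 for a single straight street, ln 4 for an orthogonal grid,
  ln 36 ≈ 3.58 at the uniform maximum. Bins are centred on multiples of the
  bin width so cardinal bearings sit mid-bin rather than on an edge —
  floating-point jitter around a bin boundary cannot move mass between
  bins, and invariance under rotations by whole bin widths is preserved.
  Length weighting (vs counting edges) is the convention adopted here; it
  makes the measure invariant to how a long street is split into edges.

## The statistics layer

Three analysis steps, mirroring the study design the pipeline implements:

1. **Controls vs patients** on every variable: Welch two-sample t test when
   both samples pass a Shapiro–Wilk normality check at α = 0.05, otherwise
   a two-sided Wilcoxon rank-sum test. The gate's outcome is recorded in
   every result row, so which path fired is always auditable. (The
   normality test and the unequal-variance default are this package's
   choices; Welch is the safer t.)
2. **Control-all / patient-accompanied / patient-alone**: a linear mixed
   model per variable, `value ~ condition + (1 | participant)`, fitted by
   REML. The two patient conditions come from the same individuals; the
   shared random intercept carries that dependence. The omnibus test is the
   Satterthwaite F on the condition term; the three pairwise contrasts
   (estimated marginal means) are Benjamini–Hochberg adjusted. A singular
   fit (zero between-participant variance) falls back to ordinary least
   squares with a logged warning; a constant response short-circuits to
   F = 0, p = 1.
3. **Controls / patients with disorientation / patients without**: one-way
   ANOVA vs Kruskal–Wallis under the same normality gate, with pairwise
   post hocs (t or rank-sum, matching the omnibus family) run only when the
   omnibus is significant, FDR-adjusted.

Correlations with external scores use the same gate (Pearson/Spearman).
Participants missing a variable (e.g. mean Fréchet distance with fewer than
two outings) are dropped pairwise per variable.

## The synthetic cohort generator

The generator plants everything the pipeline later estimates, so every
stage can be validated against ground truth. Defaults describe the study
conditions the package emulates: 18 controls and 15 patients, 14 tracking
days, sampling at 3 s for roughly 13/18 controls and 9/15 patients (5 s for
the rest), 10 m position error SD, spikes at 1 per 1000 fixes displaced
300–1000 m, and per-condition outing processes patterned on the target
cohort's scale — daytime/nighttime Poisson rates 1.89/0.38 per day for
controls, 1.36/0.21 for patients accompanied and 1.02/0.01 for patients
alone; walking distance per outing lognormal with means 1.94 / 1.33 /
0.94 km; and a vehicle-trip mixture (probability 0.75 / 0.60 / 0.35, mean
28.6 / 27.2 / 10.4 km) that brings total distance per outing to roughly
23 / 18 / 5 km. Walking speed is Normal(4.5, 1) km/h truncated above
0.5; vehicle speed Normal(40, 10) truncated above 15 — distributions that
deliberately straddle the mode-classification thresholds. Per-participant
gamma factors (CV 0.35 on rates, 0.45 on distances) supply the
between-participant spread a mixed model needs and put the cross-sectional
SDs on the scale reported for such cohorts.

Outings are out-and-back trips along a participant's habitual routes (5
route bearings per participant, reused across outings with per-waypoint
heading jitter), sampled on the device's time grid from a piecewise-linear
motion profile: walk out, optionally drive, an optional mid-outing stop of
5–15 min at the far point (only its first 2 minutes are recorded), and the
mirror-image return. After returning, 2 minutes of at-home fixes are
recorded before the device sleeps; a daily at-home "heartbeat" block at
03:00 keeps zero-outing days observable. Sub-100 m strolls (35–45 m out
and back, beyond the geofence but below the outing threshold) are planted
at a configurable rate as known negatives.

**The error model is deliberately not white noise.** Receiver error is
strongly autocorrelated over seconds to minutes; modelling it as
independent 10 m draws per fix would inflate every recovered path length
several-fold at walking speeds (≈12 m of spurious path per 3 s step),
which no real track shows. The generator uses a first-order autoregressive
(Gauss–Markov) process per axis with marginal SD `gps_sigma_m` and
correlation time `noise_tau_s` = 300 s, restarted at every recording gap
(bias decorrelates while the receiver sleeps). The residual path inflation
at walking speed is ≈13%, consistent with raw consumer GPS.

Spikes are planted as single-fix displacements of 300–1000 m on
pedestrian/stationary fixes that do not immediately follow a gap: a
displacement of that size on a 5 s vehicle fix can be kinematically
plausible (≤ 278 m is reachable at the 200 km/h ceiling), and one on the
first fix after a gap is indistinguishable from real movement even in
principle, so neither makes a well-posed artifact. Outing start times keep
a 3-minute guard away from the 06:00/18:00 band edges: geofence-based
detection necessarily dates an outing ~25 s after the true departure, so a
start planted on the boundary has no well-defined band.

What the generator does **not** emulate: routing on real street networks
(trajectories are synthetic polylines, not map-matched paths), activity
purposes, seasonal daylight effects, urban-canyon error bursts beyond the
AR model, and any behavioural mechanism of disorientation — the
disorientation flag is a label, not a behaviour. Passing recovery tests on
this generator therefore demonstrates that the pipeline measures what it
claims on data with the stated sampling, gap, noise and spike structure;
it does not validate the scientific interpretation of those measures on
real cohorts.

## Numerical choices and edge cases

* Geodesic distances are haversine on a sphere of radius 6371.0088 km
  (sub-0.5% vs the ellipsoid at these scales); buffer geometry and the
  all-pairs Fréchet computation use the local projection as described.
* Truth-vs-estimate comparisons of outing *rates* use realized
  outings-per-recorded-day: a day with no outdoor navigation is removed by
  day cleaning by definition, so the rate denominator is recorded days, not
  calendar days, in both the truth and the pipeline.
* Degenerate inputs: traces with < 2 fixes pass the spike filter unchanged;
  single-fix outings have zero distances (flagged); zero-outing
  participants report zero rates and missing per-outing variables; fewer
  than two outings leave the Fréchet mean undefined; empty diaries leave
  all outings `unknown`; a trailing window with no speed estimate is
  dropped (logged).
* The BH adjustment is `stats::p.adjust(method = "BH")`; it agrees exactly
  with the step-up formula, preserves order and is monotone in the sorted
  p values. (Reapplying it to its own output is not an identity in general;
  the adjusted values are reported once.)
* Validation problem sizes: the full-cohort recovery runs use the default
  18 + 15 × 14-day cohort (~1M fixes); oracle equivalence uses 200 random
  trajectory pairs of length ≤ 8 against exhaustive coupling enumeration;
  null calibration uses 500 simulations per test family; buffer-count
  equivalence uses 50 random environments. These sizes make Monte-Carlo
  tolerances (3 SEs; [0.03, 0.07] for nominal 0.05) tight enough to catch
  real defects.

## Known limitations

* Outing detection dates departures at the geofence crossing, ~25 s late at
  walking pace; band labels of outings genuinely started *on* a band edge
  are therefore ambiguous.
* Sustained 3 SD error excursions can, rarely, fabricate a ~100 m
  "outing" of tangential noise wander near the geofence or keep a
  no-navigation day alive; at the default conditions this affects of the
  order of one outing and a few participant-days per cohort.
* Walking distance inherits mode-classification granularity: fixes in the
  window that straddles a walk/vehicle transition are attributed wholesale,
  costing up to ~2 fix steps per transition.
* The geospatial layer assumes straight-segment road edges; curved roads
  must be pre-split into segments.
* p values from the mixed model rely on Satterthwaite approximation at
  n = 33; the calibration tests bound the type-I error only under the
  generator's error model.
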