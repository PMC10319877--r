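---
title: "Methods: cleaning, geomasking and validating pedestrian GPS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleaning, geomasking and validating pedestrian GPS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtrack)
```

## The data model

`pedtrack` works on cohorts of purpose-based pedestrian trips: each
participant records one walk between home and school with a phone app that
samples GPS nominally at 1 Hz. A raw track is a 7-column CSV (`course,
haccuracy, latitude, longitude, speed, time, nickname`); the nickname
carries the trip metadata (school code, teacher-assigned number, transport
mode, companionship) in bilingual tokens, and the filename prepends the trip
date. Processed files carry three extra columns on the *time-advanced*
convention: the interval `dt`, the step distance `d` and the instantaneous
velocity `v = d / dt` at row *i* all describe the interval between fixes
*i* and *i + 1*, so the last row's step fields are empty.

All distances are haversine great-circle distances with mean Earth radius
6,371,008.8 m. At the sub-10-km scale of a commute, the difference from a
full ellipsoidal geodesic is far below the 6-decimal-place coordinate
rounding of the files (~0.1 m), so the simpler metric is used throughout
and documented by its constant. Timestamps are parsed as naive local wall
clock at 1 s resolution; no trip crosses a daylight-saving boundary, so no
timezone arithmetic is performed.

## The five cleaning stages and their thresholds

The original processing of such data is typically done by eye on maps;
automating it forces every judgement into an explicit threshold. All of
them live in `cleaning_policy()` and can be overridden; the defaults are:

| parameter | default | why |
|---|---|---|
| `v_nonped` | 2.5 m/s | kept pedestrian *effective* speeds top out near 1.95 m/s; vehicles average well above |
| `v_outlier_max` | 10 m/s | above any running pedestrian (max kept instantaneous speeds ≈ 8.6 m/s), below GPS start-up jumps (up to 90 m/s) |
| `haccuracy_max` | 100 m | fixes with larger reported uncertainty carry no usable position |
| `school_radius` | 150 m | the protocol asks participants to start/stop 5–150 m from the endpoint |
| `min_records` | 30 | shorter fragments cannot form a meaningful trip |
| `max_outlier_fraction` | 0.3 | beyond this no coherent origin–destination path remains |
| `endpoint_dwell_radius` / `endpoint_dwell_min` | 20 m / 60 s | indoors, fixes accumulate around one point for minutes |

Three design points deserve comment.

*Velocity attribution.* A single displaced fix spikes **both** of its
adjacent step velocities, so a record is removed only when both its
incoming and outgoing steps exceed the cap (terminal records need only
their single adjacent step). Removing any record changes the neighbouring
steps, so the rule is iterated to a fixed point (at most 10 passes); a
single pass would mislabel the good neighbour of a spike.

*Accuracy-robust screening.* Both the unknown-mode effective-speed screen
(stage 1) and the endpoint test of OD validation (stage 2) are computed on
the accuracy-trustworthy fixes (`haccuracy <= haccuracy_max`). A start-up
burst of low-accuracy jumps can otherwise inflate a walker's effective
speed past the vehicle threshold, or displace the apparent trip start
hundreds of meters from the school, and misroute a perfectly good trip
before the outlier stage ever sees it.

*Discard accounting.* Only velocity/accuracy outliers count toward the
whole-trip discard fraction; collapsing a terminal dwell is expected
behaviour near a school building, not evidence the trip is broken. The
dwell collapse keeps the segment's first record, so the trip still ends at
the school.

## Geomasking and the disclosure-risk model

To protect home locations, each surviving trip loses a window of movement
at its home-side end: the first *t* seconds of movement for home-to-school
trips, the last *t* seconds for school-to-home trips, with *t* drawn
uniformly on the **integers** 20..50 s (the distribution is otherwise
unspecified; integers match the 1 s cadence). The window is measured in
elapsed time from the first (or last) *moving* fix — leading or trailing
zero-velocity records are not allowed to absorb it — and an elapsed-time
window rather than a record count makes the mask robust to temporal gaps.
The removed piece is always a contiguous prefix or suffix, and one draw is
made per trajectory (the dataset has one-way trips only).

The privacy gained is quantified by spatial k-anonymity: assuming a
constant walking speed `v_assumed = 1.5 m/s` for everyone, the masked
endpoint is consistent with any of the

$$k = \text{density} \cdot \pi (v t)^2$$

housing units inside the circle of radius *d = v·t*, and the disclosure
risk is 1/k, strictly decreasing in both housing density and *t*. The
shipped district table (urban surface in km², housing units, and the
schools located in each zone) reproduces its printed per-district risks at
*t* = 50 s and their unweighted mean of 2.72 × 10⁻³:

```{r risk}
district_housing()[, c("district", "surface_km2", "housing_units",
                       "density", "risk")]
average_disclosure_risk(district_housing(), t = 50)
```

One printed density in the source table (Viladecans, 6,355.95 units/km²)
differs from the exact quotient of its own printed inputs
(24,221 / 3.811 = 6,355.55) by 0.006%; the package computes the exact
quotient, which reproduces the printed risk at 3 significant figures.

## Interpolation and the validation statistics

The app's nominal 1 Hz cadence is broken by connection gaps: about 17% of
steps exceed 1 s, but 99.8% stay within 4 s, so gaps are short. Stage 5
fills every missing integer second by linear interpolation of latitude and
longitude (and the carried columns) against time. Interpolating in
coordinate space rather than along great circles differs by well under a
millimeter at city scale. Original fixes are preserved exactly; after
interpolation every `dt` is 1.0 and `d` equals `v` numerically. Endpoints
and total duration are invariant; the path length is invariant on collinear
segments and changes only at rounding level otherwise.

Validation statistics (`cohort_msd()`, `cohort_vacf()`, `velocity_pdf()`):

- **MSD**: squared displacement averaged over *all* time origins within a
  trip, then across trips with equal weight. Averaging over all origins
  rather than only the trip start uses every pair and is the standard
  estimator; it is (v τ)² for ballistic motion and linear in τ for
  diffusion, both of which are verified as closed-form tests.
- **Velocity autocorrelation**: computed on u = ln(v/v_m) per trip
  (v_m includes zero-velocity steps in its mean; u itself is undefined at
  v = 0, and those steps are excluded and counted). The per-trip
  autocovariance at lag τ is normalized by the trip's lag-0 variance, so
  C(0) = 1 identically; trips with zero variance are skipped.
- **Confidence bands**: 95% bootstrap over trips (the between-trip
  resampling respects the strong within-trip correlation). The default is
  500 resamples, seeded.
- **Histograms**: v binned at 0.1 m/s on [0, 9]; u at 0.1 on [−5, 2].

Comparing a cohort before and after interpolation
(`compare_interpolation()`): D, T and v_eff are invariant per trip, while
the pooled mean instantaneous velocity shifts slightly *down*, because each
gap step is replaced by several 1 s sub-steps that all inherit the gap
step's (slower, chord-averaged) velocity — the shift concentrates in the
low-velocity part of p(v), as the paired histograms show.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` exists so every stage is testable without the original
field data. Its defaults encode the study conditions:

- per-participant mean walking speed lognormal with mean 1.5 m/s and sd
  0.25 m/s; per-second speeds vary around that mean with cv 0.2;
- trip durations uniform on 300–700 s (matching observed quartiles of
  roughly 300/460/600 s);
- a staircase street walk: headings alternate between two orthogonal
  directions in exponentially distributed segments (mean 30 s), emulating a
  street grid without any map dependency, and giving u a realistic
  short-range autocorrelation;
- temporal gaps with P(Δt = 2, 3, 4) = 0.12, 0.03, 0.018 and
  P(Δt > 4) = 0.002, so P(Δt > 1) = 0.17 and P(Δt ≤ 4) = 0.998;
- GPS receiver error as an AR(1) process per axis with marginal sd 3 m and
  lag-1 correlation 0.998 at 1 s. Receiver error drifts slowly rather than
  flickering white; a white 3 m error would inflate step velocities far
  beyond anything seen in kept field data (where instantaneous and
  effective mean speeds nearly coincide), while the slow drift reproduces
  that near-coincidence;
- start-up bursts on 30% of pedestrian trips: up to 6 fixes jumping at
  20–90 m/s with accuracy radii of 150–500 m (activation fixes are both
  displaced and self-reportedly untrustworthy);
- terminal dwell on 20% of trips: 60–180 s of fixes jittering within a few
  meters;
- contaminants: 25% declared vehicle trips, 10% undeclared vehicles
  (~8 m/s), 8% scatter blobs around the school, 8% coherent walks with no
  school endpoint.

Trips are generated *backwards* from the school: a staircase walk of the
drawn duration leaves the school, and its far end becomes home, so the home
distance (~300–1,100 m) is emergent from duration × speed rather than drawn
first. This guarantees clean trips are OD-valid by construction and mirrors
the privacy design — the home point itself is never emitted. Every record
carries a truth label (`clean` / `outlier` / `dwell`) and every trip a
class, so `truth_eval()` can score each stage's precision and recall
exactly.

The generator does **not** emulate: real street networks or route choice,
stops at crossings, demographic or school-size heterogeneity, multipath
urban-canyon error structure, or device-specific accuracy models. Passing
tests on synthetic cohorts therefore demonstrate the pipeline's *contracts*
(what is removed, what is preserved, what is invariant), not its behaviour
on every pathology of real receivers.

## Numerical choices and degenerate inputs

- Ties/duplicates on read: records are time-sorted; duplicated timestamps
  keep the first occurrence; out-of-range coordinates are dropped — both
  with a message, never silently.
- Coordinates are written with 6 decimal places; round-trips are exact at
  that precision.
- `interpolate_track()` refuses non-integer-second timestamps rather than
  snapping silently (the shipped readers cannot produce them; hand-built
  tracks might).
- Degenerate trips (single instant, zero duration, all-zero velocities)
  raise informative errors rather than NaN propagation; a risk computation
  with zero density or zero window is an explicit error, not `Inf`.
- Direction (home-to-school vs school-to-home) is not encoded in the
  nickname; it is supplied per school in the run configuration or inferred
  from which endpoint lies nearer the school (the nearer endpoint is taken
  as the destination).
- The ± values in the summary tables are standard errors of the mean;
  single-trip groups report `NA` rather than 0.

## Problem sizes used by the tests

The shipped tests and the acceptance script run on synthetic cohorts of 40
to 1,000 trips (the geomask window check uses 1,000 trips; cleaning
recovery uses 100 contaminated trips; parameter recovery uses 600 clean
trips; everything else uses a few dozen), chosen so the whole suite
completes in a few minutes while keeping Monte-Carlo standard errors well
inside the asserted tolerances.

## Known limitations

- The cleaning thresholds automate judgements that were originally visual;
  on real data their defaults should be reviewed against a sample of maps.
- The disclosure-risk model assumes uniform housing density within each
  district circle and a constant walking speed for all participants; it is
  a deliberate order-of-magnitude tool, not a cadastral computation.
- Linear interpolation slightly increases short-lag velocity correlation
  (inserted sub-steps share one velocity); analyses of C(τ) at τ of a few
  seconds should prefer the processed, non-interpolated files.
- Course (bearing) is linearly interpolated like the other carried columns,
  which is wrong across the 0°/360° wrap; the column is carried for
  completeness and never used in computation.
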