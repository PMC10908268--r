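---
title: "Analyzing cow lying behavior from leg-worn accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing cow lying behavior from leg-worn accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovact)
library(dplyr)
```

## The measurement model

A triaxial accelerometer strapped to the outside of a cow's metatarsus
measures *proper* acceleration: the vector sum of a static gravity component
(1 g pointing skywards when the sensor is at rest) and the dynamic
acceleration of the leg. After mapping the sensor's XYZ channels onto
body-relative axes — *forward*, *upward* (along the leg toward the torso),
and *right* — the gravity component encodes sensor tilt and hence posture:

* standing: the leg is near-vertical, so gravity loads on the upward axis
  (`acc_up` ≈ 1 g);
* lying: the leg is near-horizontal, `acc_up` drops toward 0, and gravity
  shifts onto the right axis (toward ±1 g when the cow lies on the
  instrumented side) and/or the forward axis (when the free leg is bent
  toward the head).

Everything in this package is driven by that shift.

## Posture classification

`add_lying()` implements a three-step rule:

1. **Gravity extraction.** The upward channel is filtered to its static
   component, by default with a centered moving median over a 10 s window
   (`window_size`), alternatively with a zero-phase (forward–backward)
   Butterworth low-pass (`filter_method = "butterworth"`, default first
   order, 0.1 Hz cutoff). The median window in samples is forced odd so the
   center is unambiguous, and shrinks to the available samples at the
   recording edges — edge bouts are flagged incomplete downstream anyway, so
   no samples are sacrificed to padding.
2. **Thresholding.** Samples with a filtered upward value below `crit_lie`
   (default 0.5 g) are lying; at or above it, standing. Since a resting
   sensor reads 1 g, the default corresponds to a leg angle of
   arccos(0.5/1) = 60° from vertical. Standing is defined as "not lying", so
   a value exactly at the threshold is standing.
3. **Minimum-duration correction.** Interior lying bouts shorter than
   `minimum_duration_lying` (default 30 s) are relabeled standing and merged
   with their neighbors. This removes the classic false positive: a standing
   cow lifting the instrumented leg toward horizontal for several seconds
   (self-grooming). True lying bouts under 30 s are rare, so the default
   trades them away deliberately; lower the minimum to hunt micro-bouts
   (~8 s ones exist, e.g. on pasture). A standing minimum
   (`minimum_duration_standing`) exists but is off by default and not
   recommended — false standing inside true lying is not physically expected,
   and short standing bouts genuinely occur when cows switch lying side.
   Each pass runs once (lying first), not iterated to a fixed point, so one
   correction cannot cascade into removals the rule never described.

Bouts are maximal runs of one posture. A bout starts at the timestamp of its
first sample and ends at the first sample of the next bout; the last bout
ends at the final timestamp. Durations therefore tile the recording span
exactly. The first and last bouts of each cow are truncated by the recording
edges and marked incomplete; they are exempt from the minimum-duration rule
(their true duration is only bounded from below) and their durations are
suppressed (`NA`) in summaries unless `calc_for_incomplete = TRUE`.

## Lying laterality

`add_side()` assigns one side to each whole lying bout by comparing the
median of the bout's raw right-axis values with `crit_left`. When the cow
lies on the instrumented side the right channel sits reliably near +1 g
(left-leg sensor) or −1 g (right-leg sensor); on the opposite side the free
leg's placement can push the value anywhere between ∓1 and ~0. The threshold
is therefore offset toward the sensor side: +0.5 g if `left_leg = TRUE`,
−0.5 g otherwise. The median rule is equivalent to asking which side of the
threshold the majority of samples falls on. The median is taken on raw,
unfiltered values: bout-length medians are already extremely robust, and
filtering would leak neighboring standing samples into short bouts. An exact
tie (median equal to the threshold) is assigned to the side away from the
sensor, with a warning — the sensor-side signature is the reliable one, so a
non-signature median is better read as "not on the sensor side".

## Activity proxies

`add_activity()` computes per-sample activity measures from all three axes:

* **DBA** (dynamic body acceleration): raw acceleration minus the per-axis
  gravity estimate (same filters and defaults as the posture step).
  `L1DBA` = |fwd| + |up| + |right| (the wildlife literature's ODBA) and
  `L2DBA` = √(fwd² + up² + right²) (VeDBA), in g.
* **Jerk**: the backward finite difference of raw acceleration divided by
  the actual timestamp step, in g s⁻¹, with `L1Jerk`/`L2Jerk` norms.
  Differencing removes the static gravity component by itself, which is why
  jerk is computed on the raw signal rather than on DBA. The first sample of
  each cow has no predecessor; its jerk is `NA`, not 0, because a zero would
  bias bout means.

The L2 norms are Euclidean magnitudes and thus invariant under rotations of
the sensor frame; the L1 norms are not. (Note that exact pipeline-level
rotation invariance of `L2DBA` additionally requires a linear gravity
filter — the Butterworth option. A moving median applied per axis is not
equivariant under rotation, so tiny discrepancies appear with the default
filter; the norm identity itself always holds.)

With `adjust = TRUE` (default) activity is set to exactly 0 on samples
inside lying bouts: lying is inactive by definition. This requires
`add_lying()` first. With `adjust = FALSE` raw values are kept but should be
interpreted cautiously — the instrumented leg is pinned when the cow lies on
it, so unadjusted lying activity is biased by lying side. Tables carry no
hidden state: to compare adjusted and unadjusted values, run
`add_activity()` twice.

## Summaries

`summarize_bouts()` returns one row per bout (duration, side, mean of each
activity column). `summarize_intervals()` aggregates per cow over
consecutive half-open intervals `[start, end)` of fixed length, anchored by
default at midnight (UTC) of the earliest day in the data — the convention
under which "daily lying time" is usually reported. Durations are exact
overlaps of bouts with the interval. Bout counts and mean bout durations use
fractional-overlap weights: a bout contributes `overlap/duration` to each
interval it touches (a bout 30% inside an interval counts 0.3 there and 0.7
next door), so interval totals are never inflated by boundary-straddling
bouts and weights sum to 1 per bout. Any weighted quantity touching an
incomplete edge bout is `NA` unless `calc_for_incomplete = TRUE`; missing
values propagate rather than being silently dropped. Mean activity per
interval is the plain mean over the interval's samples, which for uniformly
sampled data is already the time-weighted mean.

`extract_liedown()` / `extract_standup()` return the annotated samples in a
closed window `[t − sec_before, t + sec_after]` around each observed
transition, where the transition time is the first sample of the new
posture — the same convention as bout boundaries, reproducible and at worst
one sample late. Recording edges are not transitions; windows clipped by an
edge are flagged truncated.

## The synthetic-data generator

The package validates itself against simulated recordings with known ground
truth (`sample_schedule()`, `sample_leg_lifts()`, `render_accel()`,
`simulate_cows()`). Defaults encode the behavior of lactating dairy cows:
9–11 lying bouts per day, bout durations 60–100 min, total daily lying time
8–13 h (the total is drawn only from the part of that band jointly feasible
with the bout count and duration band, then individual durations are
rescaled within the band to hit it). The day starts and ends standing, so
every simulated lying bout is interior. Rendering places the unit gravity
vector per the posture: `(0, 1, 0)` standing, right ≈ ±1 on the sensor-side
axis when lying on the instrumented side, and for the opposite side a
direction drawn once per bout from an arc between the right axis and the
forward axis (5°–85°), emulating the free leg being placed and held.
Posture transitions are smooth 5 s rotations (spherical interpolation, so
the gravity magnitude stays 1 g); leg-lift artifacts rotate the vector
toward horizontal (60°–85° tilt) for 5–25 s inside standing episodes.
Standing noise defaults to σ = 0.3 g, band-limited to 0.5–3 Hz where the
sampling rate resolves that band (white otherwise — e.g. at the 1 Hz used in
most tests), lying noise to σ = 0.05 g. Injected side switches use a 20 s
standing gap: a standing bout shorter than half the 10 s filter window is
mathematically invisible to the gravity filter at any sampling rate, and the
simulator's job under defaults is to produce switches the method can see.

What the simulator does *not* emulate: rumination and grazing head
movement (irrelevant at the hind leg), gait periodicity beyond band-limited
noise, step counts, sensor drift or calibration error, and atypical
transition movements. Passing recovery tests on simulation therefore
demonstrates the pipeline's correctness under its own measurement model, not
field accuracy on any particular logger.

## Numerical choices

* Median windows: seconds are converted to samples with `round()`, bumped to
  odd; windows shrink asymmetrically at edges.
* Butterworth: coefficients from `signal::butter()`; forward–backward pass
  over an odd-symmetric extension of `max(3(order+1), 4/cutoff seconds)`
  samples per end, long enough for the zero-state transient to decay below
  ~1e−11 before real data begin.
* Equality at thresholds: posture threshold → standing; laterality tie →
  side away from the sensor, with a warning.
* Timestamps are timezone-naive (parsed as UTC); duplicate timestamps within
  a cow are an error; gaps longer than 10× the nominal interval warn and are
  then treated as contiguous for filtering — interpolation would fabricate
  data. Jerk across a gap uses the actual timestamp difference.
* Minimum-duration comparison uses seconds computed from timestamps, not
  sample counts, so the rule is sampling-rate independent.

## Problem sizes used in the test-suite

Recovery checks run 100 independent simulated days at 1 Hz (86,400 samples
each) through the full pipeline: with default parameters, every day's lying
bout count matches the schedule, the daily lying-time error stays below 1%,
and every bout's side is recovered. Filter and segmentation oracles are
brute-force re-implementations checked on 1,000 short random series. These
sizes keep the whole suite under a couple of minutes on one CPU while
exercising day-scale data; results are insensitive to making them larger.

## Workflow example

```{r workflow, eval = FALSE}
sim <- simulate_cows(n_cows = 1, n_days = 1, rate = 1, seed = 42)
ann <- sim |>
  add_lying() |>
  add_side(left_leg = TRUE) |>
  add_activity(measures = c("L2DBA", "L2Jerk"))
summarize_bouts(ann)
summarize_intervals(ann, interval = "1 day")
plot_posture(ann)
```

A thin command-line wrapper (`inst/exec/bovact`) chains the same functions
from a flat YAML configuration (`read_run_config()` documents the keys;
YAML was chosen because a parser for it ships with R's ecosystem here), with
subcommands `simulate`, `analyze`, `summarize`, and `extract-transitions`.

## Known limitations

* Defaults are tailored to adult cows; for calves or other species the
  thresholds and minimum durations need re-validation ("off-label" use).
* No resampling: data are assumed uniformly sampled at the inferred nominal
  interval; heavy jitter or drift triggers warnings, not correction.
* Standing is a catch-all (includes walking); the package does not separate
  locomotion from stationary standing.
* In-memory processing only; a year of 20 Hz data for many cows will be
  memory-hungry.
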