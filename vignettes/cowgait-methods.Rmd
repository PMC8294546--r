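---
title: "Methods: IMU-based kinematic gait analysis of walking cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU-based kinematic gait analysis of walking cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowgait)
```

## Scope and model

`cowgait` quantifies the straight-line walk of dairy cattle from body-mounted
inertial measurement units (IMUs): 6-axis sensors (3-axis accelerometer,
3-axis gyroscope, 200 Hz) on the four distal limbs
(metacarpus/metatarsus) and on up to seven upper-body landmarks (sacrum,
withers, back, left/right tuber coxae, head, collar). Every recording starts
with at least five seconds of standing still, used as the gravity and
zero-orientation reference.

The walk is treated as a lateral-sequence quadruped gait: footfall order
LH → LF → RH → RF, with the left-hind (LH) claw-on as the stride reference.
All analyses are built on the per-limb claw-on/claw-off event sequences:

* **Temporal parameters** — stance duration (claw-on to claw-off), stride
  duration (claw-on to claw-on), and bipedal/tripedal support durations
  (intervals during which exactly two or exactly three named limbs are in
  stance). Because cows walk at a self-chosen pace, each duration is also
  *speed-normalized* by dividing by the LH stride duration of its stride,
  giving duty factors.
* **Distal limb angles** — the sagittal-plane angle of the metacarpus/
  metatarsus, re-zeroed at each stride's midstance; its per-stride maximum
  (protraction, positive) and minimum (retraction, negative).
* **Vertical displacement** — upper-body vertical excursion per stride,
  obtained by cyclic double integration of the gravity-corrected vertical
  acceleration.

## Event detection

Claw-on/claw-off detection works on the mediolateral gyroscope channel of
each limb sensor. During swing the distal limb protracts rapidly (large
positive angular rate); during stance it retracts slowly (moderate negative
rate). The detector:

1. low-pass filters the rate (Butterworth order 2, zero-phase, default
   10 Hz) and marks *swing spans* where the rate exceeds an adaptive
   threshold — a fraction (default 10%) of the local envelope peak, with an
   absolute floor so a standing cow yields no events;
2. walks outward from each swing span on a lightly filtered copy (default
   50 Hz) to the sign changes of the rate: the upward zero crossing before
   the swing is claw-off, the downward crossing after it is claw-on. The
   crossings are located by extrapolating the steep swing-side branch, not
   by interpolating across the corner, which would bias towards the shallow
   stance branch;
3. refines claw-on to the hoof-impact landmark: the earliest interval
   within ±50 ms whose accelerometer jerk exceeds 20% of the local jerk
   peak, provided that peak is decisively impact-like. Ties snap to the
   earlier peak; events are timestamped on the sampling grid; stance is the
   closed-open interval [claw-on, claw-off).

Minimum stance and swing durations (100 ms each) suppress spurious spans.
On noise-free synthetic walks the detector recovers every event within one
sample; at realistic sensor noise (2 deg/s gyro, 0.5 m/s² accelerometer)
events stay within a few milliseconds, well inside the 30 ms band the tests
enforce.

## Stride segmentation and regularity screening

Strides run from one LH claw-on to the next. Strides without a claw-on of
every limb inside their window (recording boundaries) are flagged
`incomplete limb coverage`. The published interval selection was done by
eye from video; `regularity_screen()` operationalizes it: a stride is
excluded when any limb's stance duration deviates from that limb's running
median by more than 25% (configurable), or when the support count reaches 0
or 4 limbs for longer than a tolerated duration (default 0.05 s). Contiguous
included runs form analysis intervals, capped at four per measurement
(longest kept), mirroring the published selection protocol.

## Orientation and limb angle

Orientation uses a quaternion complementary filter: per sample the
quaternion is propagated by the body angular rate (midpoint rule) and then
rotated a fraction `1 - alpha` (default gyro weight `alpha = 0.99` per
sample at 200 Hz, i.e. a time constant of roughly half a second) towards
agreement with the accelerometer gravity direction. The correction is
gated out when the accelerometer magnitude is far from 1 g (impacts). The
sagittal angle is the rotation about the mediolateral axis, protraction
positive. Each stride's angle is re-zeroed at that limb's midstance
(temporal midpoint of the stance), so maxima are reported relative to the
midstance orientation; strides whose maximal retraction is non-negative or
maximal protraction non-positive are flagged and excluded from summaries
but never deleted. Whether the extrema are taken over the full stride or
the swing only is ambiguous in the field; the full stride is used here —
for the trajectory family at hand the two coincide.

## Vertical displacement by cyclic double integration

Accelerations are rotated to the gravity-aligned frame, gravity is
subtracted, and the vertical component is double-integrated stride by
stride. Drift removal is *cyclic*: after each integration the line through
the first and last sample is removed, forcing equal velocity and equal
displacement at the stride boundaries. For stride-periodic motion this is
exact; a least-squares detrend is deliberately not used, because a sinusoid
over a whole number of periods has a non-zero regression slope on time and
the resulting correction leaks a quadratic into the displacement. Strides
shorter than 0.3 s or longer than 3 s are skipped. The core stride is
linearly interpolated to 100 samples (0 = LH claw-on, 100 = next LH
claw-on) and zero-meaned; 10% padding blocks on either side are resampled
separately (10 samples each) and kept outside the 0–100 scale, so the
100-point curve always spans exactly one stride.

## Curve statistics

Curve sets (per limb for angles, per cow and location for displacement) are
summarized by the pointwise median curve, the pointwise median absolute
deviation (no consistency scaling), and the *most typical curve*: the member
minimizing the summed pointwise distance to all other members. The
distance is root-mean-square over the 100 samples by default (mean absolute
as an alternative); the definition is pairwise rather than
distance-to-median — both are available and agree on well-behaved sets.
Ties break to the earliest stride. Mean claw-on/claw-off timings per limb,
as a percent of the stride and wrapped into [0, 100), provide the footfall
marks drawn under the curves.

## Statistical summaries

Medians get percentile bootstrap 95% confidence intervals (default 2000
resamples, stride-level resampling; cow-level cluster bootstrap by option).
Group contrasts (limbs, limb pairs) use a linear mixed model fitted by REML
with `lme4`: response ~ group + stride-duration deviation + (1 | cow),
where the covariate is each stride's deviation from the median LH stride
duration and is omitted for duty-factor responses (already
speed-normalized). Group-level means with Wald intervals and a pairwise
CI non-overlap flag are reported — the non-overlap flag, not a p-value, is
the inferential device. Residuals and random-effect estimates are exported
for external diagnostics. Singular fits or single-cow data fall back to
group-wise bootstrap intervals with the method recorded.

## The synthetic-walk simulator

Because no public raw recordings exist at the signal level, the package
ships a simulator whose defaults are the published group medians for sound
cows, and the test suite validates the pipeline by parameter recovery
through synthesized raw signals.

* **Footfalls** — stance k of each limb occupies
  `[(k + phi) T, (k + phi + d) T]` with stride duration `T = 1.34 s`,
  quarter-cycle offsets (LH 0, LF 0.25, RH 0.5, RF 0.75), duty factors
  LF 0.68, RF 0.69, LH 0.64, RH 0.64, and independent Gaussian boundary
  jitter (default SD 0.01 s, a realistic stride-to-stride variability of
  under 1% of the stride). Jitter draws that would invert an event pair are
  resampled a bounded number of times, then rejected loudly.
* **Limb angle trajectory** — during stance a smooth monotone descent from
  the protraction maximum to the retraction maximum that passes through
  zero exactly at midstance with zero end slopes; during swing a raised
  cosine back up. The trajectory is C1, its extrema are exactly the
  programmed maxima (defaults: +25/+26° front, +24/+23° hind protraction;
  −46° front, −29/−30° hind retraction), and its only rate sign changes
  are at claw-on and claw-off — the geometry the detector exploits. The
  gyroscope emits the analytic derivative; the accelerometer emits gravity
  rotated by the same angle plus a short decaying 40 Hz burst at each
  claw-on (the impact landmark) plus white noise.
* **Upper body** — vertical displacement is two stride-locked harmonics,
  `z(p) = h1 cos(2π(p − p1)) + h2 cos(4π(p − p2))` on the (jittered) LH
  stride phase `p`. Default phases put the sacrum peaks at 25% and 75% of
  the stride (hind-limb midstances), the withers at 0% and 50%, the back
  just before both, and make the first tuber-coxae peak the higher one on
  the left side (mirrored on the right). Amplitudes follow the published
  excursions: ~0.045 m peak-to-peak for sacrum and withers, ~0.025 m for
  the back, ~0.1 m for the tuber coxae — the published text and table are
  not fully consistent on the tuber-coxae scale, and the text value was
  taken. Head and collar add low-frequency sinusoidal wander (default SD
  0.02–0.03 m) emulating non-stride head motion. The vertical
  accelerometer channel is the analytic second derivative plus gravity, so
  the discrete identity `second difference of z = emitted specific
  acceleration − g` holds to O(Δt²) and double integration is testable
  against truth.
* **Calibration and ramps** — every trial is prefixed by 5 s of standing
  still plus a 1 s lead-in; the amplitude envelope ramps in over the first
  stride so signals stay continuous. The first stride is therefore not
  stride-periodic and recovery oracles use steady-state strides.
* A single integer seed drives all randomness; identical seeds give
  byte-identical trials.

The simulator emulates timing structure, sensor geometry, impact landmarks
and additive white noise. It does **not** emulate soft-tissue artifact,
sensor mount wobble, gait pathology, turns, or drifting walking speed — so
passing recovery tests demonstrates correctness of the algorithms under the
stated signal model, not field robustness on lame or turning cows.

## Numerical and design choices

* Detection thresholds (10% of envelope peak, 100 ms minimum phases,
  ±50 ms impact window) are configuration keys with the defaults above;
  the envelope uses an O(n) block-maximum approximation of a 2.5 s rolling
  maximum.
* Events are sample-timestamped; no sub-sample event times are reported.
* The angle extrema tolerate reconstruction error of well under 1° noise
  free; the dominating term is the accelerometer correction during swing,
  bounded by the filter gain.
* Support-phase durations come from an exact sweep over the union of
  stance boundaries; "bipedal" and "tripedal" mean *exactly* two/three
  limbs grounded (a configuration partition). Intervals split by a stride
  boundary belong to the stride containing their midpoint. Quadrupedal and
  single-support intervals are recorded but flagged as non-standard.
* Elementary interval durations are validated against a 1 ms rasterization
  oracle (agreement within 2 ms over random walks).
* Test problem sizes — 5 synthetic cows × 42 strides for temporal
  recovery, 12–40 strides for angle and displacement recovery, 500
  Monte-Carlo repetitions for bootstrap coverage — were chosen so each
  check carries clear statistical power while the whole suite runs in a
  few minutes on one CPU.

## Known limitations

* The claw-event detector is designed against the simulator's signal
  geometry (validated against its ground truth); on real recordings its
  thresholds may need retuning, and no force-plate validation is possible
  from IMU data alone.
* The published ipsilateral bipedal support fraction (≈0.08) is not exactly
  reproduced by the idealized quarter-phase model (which gives 0.06–0.07);
  real cows deviate slightly from quarter offsets, and the phase offsets
  are parameters for exactly that reason.
* Absolute vertical displacement amplitude is recovered only up to the
  per-stride drift correction; between-stride (sub-stride-frequency)
  motion is deliberately discarded.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_trial(gait_params(n_strides = 20),
                      noise = noise_params(seed = 5))
report <- run_pipeline(sim$trial, load_config(), out_dir = "report")
report$temporal_summary
report$angle_summary
report$footfalls
```
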