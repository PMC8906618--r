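---
title: "Quadruped gait analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadruped gait analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadgait)
```

This vignette explains the models behind `quadgait`, the tunable
parameters and their defaults, what the gait simulator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Coordinate convention and data model

All computation happens in a canonical laboratory frame: `x` positive
toward the animal's cranial direction, `y` toward its left, `z` up,
coordinates in millimetres.  On a treadmill the animal is
quasi-stationary in this frame while the belt moves under it, which is
why over-ground-equivalent distances must be belt-compensated (below).
Imports from exports with other axis conventions go through a signed
axis permutation (`axis_mapping()`), which is required to be
right-handed.

A `trial_recording` carries the 25-marker positions, frame rate, belt
speed (read from the treadmill display, a per-trial constant input — it
is never estimated from the data), condition label and an explicit
missing-sample mask.  Dropouts are never silently zero-filled: an
operation that needs a marker raises an error when more than 20% of the
samples in its analysis window are missing, and otherwise bridges
interior gaps by linear interpolation (leading/trailing gaps take the
nearest observed value).  The 20% limit is a conservatism threshold: a
denser gap structure makes interpolated kinematics untrustworthy, and
refusing loudly matches how occluded spinal markers should surface as
empty result cells rather than fabricated angles.

## Filtering

Canine marker data carry useful signal well above the 5–6 Hz cutoffs
customary in human gait work, especially for small dogs, so the default
is a 6th-order low-pass Butterworth at `fc_hz = 20` (Hz), applied
forward and backward to cancel phase delay.  The forward–backward pass
squares the magnitude response — the "order 6" names the single-pass
design.  Before filtering, each component is linearly detrended and the
trend re-added afterwards, so non-harmonic drift neither leaks through
the filter nor biases it; detrend + re-add is exactly lossless.

Two numerical choices matter:

* **Edge handling.**  The forward–backward filter is run with zero
  initial state, so the series is padded with an odd reflection about
  its endpoints — by default `max(120, n/10)` samples, about one stride
  at a 120 Hz capture rate.  One hundred twenty samples is enough for
  the slowest pole of the 20 Hz design to decay below 1e-8, which makes
  the DC gain exactly 1 to numerical tolerance.  Results within about
  one stride of the recording edges are still the least trustworthy part
  of any trial.
* **The "ideal" FFT filter** (`ideal_lowpass_fft()`) zeroes every
  spectral bin above the cutoff.  Its stopband is exactly empty, but the
  hard truncation rings near the endpoints, which is why it is kept only
  as a comparison utility and is not part of the default pipeline.  A
  cutoff equal to the Nyquist frequency keeps every bin, giving an exact
  all-pass — useful for verifying the detrend/re-add path bit-for-bit.

## Gait events

Heel strike is operationalized as the frame where the paw marker (index
5) is farthest cranial of its girdle marker (index 2: greater tubercle /
greater trochanter), toe-off as farthest caudal; both are extrema of the
signed fore-aft difference.  The signed form is used rather than 3D
distance — extrema coincide for steady treadmill gait, and the signed
signal keeps its meaning if the animal drifts on the belt.

Peak detection needs two thresholds the underlying idea ("find the
peaks") does not fix.  Both are scale-free so that the same defaults
work from a Yorkshire terrier to a bull terrier:

* minimum separation = `min_sep_frac = 0.5` × the dominant period,
  estimated from the autocorrelation of the phase signal;
* minimum prominence = `prom_frac = 0.2` × the signal's interquartile
  range.

Alternation is then enforced by keeping the most prominent extremum of
any same-kind run.  Events are detected on filtered signals, matching
the pipeline order.  Cycles span consecutive back-right heel strikes;
cycles missing an expected event are flagged incomplete, not dropped.

Two properties worth stating precisely: adding a constant offset or a
gentle linear trend (< 1 mm/s) leaves detection unchanged; and under
time *reversal* the detected events mirror but keep their kinds (a local
maximum stays a maximum), whereas under sign *negation* heel strikes and
toe-offs swap.

## Joint angles and curves

The 18 angles are unsigned interior angles in [0°, 180°] at an apex
marker between two peripheral markers, after projecting onto the
sagittal (x–z) or horizontal (x–y) plane.  No flexion/extension sign
convention is imposed — the definitions name only "the angle between the
connecting vectors", and an unsigned angle is what that yields.  3D
anatomical angles (flexion/abduction/rotation) are out of scope: they
need at least three markers per rigid segment, which this marker set
does not provide.  The caudal reference of the sagittal `L7` angle is
taken as `S5`, consistent with the horizontal `L7` definition (the only
ambiguous entry in the angle table).

Per cycle, each angle series is linearly re-interpolated onto 101 points
spanning 0–100% inclusive, so sample *i* is the angle at *i* percent of
the gait cycle.  A set of cycles is summarized by the pointwise mean and
a 95% band.  The band is, by default, the confidence interval of the
mean, mean ± t(0.975, n−1)·SD/√n; a prediction-style band (mean ±
1.96 SD) describing cycle-to-cycle spread is available via
`mean_band(type = "prediction")`.  The CI-of-mean default was chosen
because the band's downstream use is comparing *average* curves between
conditions.

## Spatio-temporal parameters

The 53-scalar registry per cycle is: stride time; cadence = 4·60/stride
time (a quadruped takes four steps per stride); speed = mean of front
and back stride distance divided by stride time; stride distance and
walking base for the front and back girdles; step distance, step height,
swing time/ratio, stance time/ratio and paw travel distance per limb;
and the 18 joint ranges of motion (max − min of the angle within the
cycle).

Design choices that were genuinely open:

* **Belt compensation.**  Over-ground-equivalent distance = lab-frame
  fore-aft displacement + belt speed × elapsed time.  Without this, all
  distances on a treadmill would be near zero.
* **Walking base** is implemented as the absolute mediolateral (`y`)
  separation of the left and right paw markers at their heel strikes —
  the standard meaning of the term, consistent with its mm unit, even
  though the source table's prose duplicates the step-distance wording.
* **Paw travel distance** is the fore-aft range of the paw marker over
  the cycle (≈ belt speed × stance duration on a treadmill); an
  arc-length reading of "distance travelled" is conceivable but the
  range is what the mm-scale trace supports robustly.
* **Swing/stance pairing.**  Stance runs from a limb's heel strike to
  its *following* toe-off; swing from that toe-off to the limb's next
  heel strike.  Both are signed and never clamped: when the next heel
  strike arrives before the toe-off — the out-of-order pattern seen on
  irregular gaits — the swing time comes out negative and the cycle is
  flagged `negative_swing_stance_*`.  Ratios are taken relative to the
  limb's own heel-strike-to-heel-strike interval, so swing + stance =
  stride and swing% + stance% = 100 hold *exactly*, flagged or not; for
  the anchor limb (back right) that interval is the cycle stride time
  itself.
* Front/back stride distance averages the left and right limbs when both
  yield values, with single-sided fallback.

## The statistical layer

Per-cycle parameter samples are screened for normality with the
Anderson–Darling test (composite case, small-sample correction, as
implemented in `nortest`); samples of fewer than 8 values are reported
as `insufficient` rather than tested, and constant samples as
`degenerate`/non-normal.  Conditions are compared per parameter with the
two-sample Kolmogorov–Smirnov test; the exact p-value is used for
tie-free samples with both sizes below 30, the asymptotic approximation
otherwise.  Frame-quantized durations (swing/stance times) produce ties;
they are deliberately *not* jittered by default, because the resulting
normality failures are an honest feature of frame-rate-limited data, not
an artefact to paper over.

Each of the 3 × 53 tests per dog–harness combination is evaluated at raw
α = 0.05 with no multiple-testing correction — the layer is a screen,
not a confirmatory analysis — and a Holm option
(`comparison_matrix(adjust = "holm")`) is available but off by default.
Calibration measured by the acceptance script: AD type-I error 4.4% at
n = 50 over 1000 null replicates.  The small-sample exact KS test is
conservative (its discrete statistic rejects ~1–3% of null cases at
n = 25 per group), which is a property of the test itself, worth
remembering when reading pass percentages.

Joint-curve deviation from the reference condition is scored per joint
as the RMS of the pointwise difference between 101-point mean curves;
a constant offset of d degrees scores exactly d, and the score is a
scaled Euclidean norm (so it obeys the triangle inequality).

## The gait simulator

`gait_spec()`/`simulate_gait_trial()` generate steady treadmill gait
with complete ground truth.  Defaults emulate a medium dog ambling on a
treadmill: stride time 0.8 s, belt 0.92 m/s, 25 cycles at 120 Hz,
step height 35 mm, walking base 80 mm, white Gaussian marker noise of
SD 0.5 mm per coordinate (capture systems of this class are
sub-millimetre accurate).  Footfall presets fix per-limb phase offsets
(fractions of a stride, order FR/FL/BR/BL): walk and amble
(0, 0.5, 0.75, 0.25) — a lateral sequence, amble with duty factor 0.58
against the walk's 0.65; pace (0, 0.5, 0, 0.5), ipsilateral limbs in
phase, duty 0.55; trot (0, 0.5, 0.5, 0), diagonal limbs in phase, duty
0.5.

Kinematics: during stance the paw is carried caudally at belt speed;
during swing it returns cranially along a cubic smoothstep with a
half-sine vertical lift — these profiles make the step-height and
paw-travel ground truths exact.  The intermediate limb markers are
placed by two-segment inverse kinematics between the girdle and a foot
point that flexes during swing, so joint-angle curves arise from a
consistent leg geometry; a stride too long for the leg raises an
"infeasible geometry" error rather than producing a dislocated limb.
Spinal markers ride a travelling lateral wave and a small vertical
oscillation (amplitudes 8 mm / 4 mm; zero gives a rigid, flat spine).
True joint ROMs are evaluated from the noise-free geometry over one
cycle — on steady gait all cycles are identical before noise.

The simulator reproduces what the pipeline needs to be validated:
periodic limb phasing, belt-carried stance, realistic marker noise,
dropouts (`degrade()`).  It does **not** emulate soft-tissue artefact,
head motion, speed drift, inter-cycle variability of a live animal, or
harness-strap mechanics; passing recovery tests therefore demonstrates
correctness of the *computation*, not robustness to every failure mode
of live recordings.  Ground-truth recovery measured by the acceptance
script on walk/amble/pace trials (25 cycles, noise 0.5 mm): stride time
exact to the frame, speed within 0.01%, walking base within 0.15 mm,
step height within 0.81 mm, joint ROM within 1.7°, stance ratio within
2.5 percentage points.  The stance-ratio figure is the one visible
method bias: zero-lag filtering rounds the sharp touch-down/lift-off
corners of the fore-aft paw signal and shifts each extremum a frame or
two toward the flatter (swing) side.  It is a property of filtering +
extremum detection, not of the parameter definitions.

## Problem sizes and determinism

The test suite and acceptance script run the full pipeline on simulated
trials of 25 gait cycles at 120 Hz (≈ 2 500 frames, 75 marker
components), the trial length typical of a homogeneous between-treats
gait section, and use 1000 replicates for test-calibration Monte Carlo;
a single trial processes in about a second.  All randomness flows
through explicit seeds (`gait_spec(seed =)` restores the caller's RNG
state afterwards), and identical inputs produce bit-identical parameter
tables — reports re-generated from the same recordings are reproducible
by construction.

## Known limitations

* 2D projected angles depend on the animal walking parallel to the
  canonical `x` axis; a skewed treadmill placement biases sagittal
  angles.
* Event detection assumes roughly periodic gait; starts, stops and
  turns violate the dominant-period heuristic.
* The walking-base and paw-travel definitions are the package's
  resolution of ambiguous prose (see above); alternative readings would
  change those two columns only.
* Statistical comparisons treat cycles as independent samples;
  within-trial autocorrelation makes the raw-α tests anticonservative in
  a way the screen does not correct for.
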