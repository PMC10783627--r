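---
title: "Methods: withdrawal detection, aiming control and analysis on a virtual rig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: withdrawal detection, aiming control and analysis on a virtual rig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocirig)
```

## What this package models

Nocifensive withdrawal assays measure how quickly a mouse withdraws its paw
from a noxious stimulus — optogenetic blue-light pulses or ramps through the
skin, radiant heat, or a force-controlled mechanical indenter. An automated
rig replaces the human tester on three fronts: it measures withdrawal
latency with millisecond precision from a photodetector monitoring red light
reflected off the paw, it terminates the stimulus in closed loop the moment
withdrawal is detected, and it aims the stimulator at the paw automatically
by driving linear actuators from pose-estimation key points in substage
video. `nocirig` implements that computational core without any hardware: a
virtual rig generates every input signal with known ground truth, so each
component can be validated end to end.

## Withdrawal detection

All three detectors share one latency convention: latency is the time from
stimulus onset to the *start* of the signal excursion that qualifies as a
withdrawal, not to the moment the qualification criterion completes.

**Reflectance (primary channel).** The 1 kHz photodetector trace is smoothed
with a *trailing* running average 27 ms wide. Baseline is the mean of the
smoothed signal over the 0.5 s epoch preceding stimulus onset. A withdrawal
is the first post-onset sample at which the smoothed signal falls strictly
below baseline − 2 mV and remains below for strictly longer than 20 ms; the
latency points back to that first sub-threshold sample. Trials with no
qualifying crossing before the stimulus cutoff (20 s for thermal work) are
censored at the cutoff, and censored trials always report
`latency = censor_time` with a flag — never a missing value — so session
tables stay rectangular.

Three alignment choices deserve note:

* *Trailing smoothing.* A centered running average would be marginally less
  biased offline, but only a causal window admits a streaming implementation
  whose output is sample-for-sample identical to the offline detector —
  which is what closed-loop stimulus termination requires. The trailing
  window delays the measured crossing by up to the window width, so
  noiseless recovery of a simulated withdrawal is exact only to within
  27 ms; the `stream ≡ offline` contract, by contrast, is exact.
* *Whole rule on the smoothed signal.* Both the crossing and the persistence
  run are evaluated on the smoothed signal. A consequence worth knowing: a
  deep raw transient shorter than 20 ms can still produce a smoothed
  sub-threshold run longer than 20 ms, because the window keeps averaging
  the transient for a window-width after it ends. The persistence guarantee
  is therefore stated on smoothed-signal excursions.
* *Strictness.* Ties with the threshold do not count as crossings, and a run
  of exactly 20 ms does not qualify: at 1 kHz a qualifying run needs at
  least 21 samples. `>` 20 ms is read literally.

At sampling rates other than 1 kHz the 27 ms window is realized as the
nearest whole number of samples (at least 1) and the realized width is
recorded on the smoothed trace.

**Paw height.** High-speed-video paw height uses the same baseline epoch and
reports the first post-onset sample rising strictly more than 6 px above
baseline. No smoothing is applied by default (smoothing is a
reflectance-channel measure; height from tracked video is already the output
of a pose model), but a window can be configured.

**Force.** During an indenter ramp, withdrawal appears as an abrupt collapse
of the measured force. "Abrupt drop" is operationalized as: force falls
strictly below 50 % of the post-onset running peak, no more than 50 ms after
that peak was set, with the rule armed only once the running peak exceeds
5 mN. The arming floor exists because a percentage rule is meaningless
inside the sensor noise floor — any noise sample is "half" of a near-zero
peak. All three constants are configurable and logged. The mechanical
threshold is the running peak at detection (the peak force immediately
preceding withdrawal) and the latency is reported at the time of that peak
sample, i.e. where the drop begins, consistent with the start-of-event
convention above. With a noiseless 10 mN/s ramp to 40 mN this yields a
latency of exactly 4000 ms and a threshold of exactly 40 mN.

**Streaming detector.** `stream_detector()` maintains the trailing mean, the
baseline accumulator and the current run length in O(1) per sample, emits
the detection event the moment the persistence criterion is satisfied
(persistence-duration after the crossing it reports), and censors at the
cutoff. Its equivalence to the offline detector is a tested contract over
1,000 seeded noisy trials.

## The virtual rig

The simulator provides every input with known truth. Its defaults are the
study conditions, chosen once:

* **Beam**: 5 mm spot at the platform (area ≈ 20 mm²), numerical aperture
  0.48, straight-edge cone divergence `r = 2.5 + z·tan(asin(0.48))` mm —
  the simplest physically motivated divergence model; the measured axial
  sensitivity of a real fiber depends on geometry we do not model, so only
  monotone behavior is asserted. Irradiance is uniform across the disc by
  default (a Gaussian profile is available; the true profile is not
  specified anywhere we could anchor it).
* **Aperture**: a 10 × 4 mm ellipse as a plausible hind-paw footprint; only
  overlap geometry matters. On-target power is the overlap integral,
  evaluated by midpoint-grid quadrature over the beam disc (no closed form
  exists for circle–ellipse overlap). An even grid keeps symmetric cases
  exact, e.g. a half-plane aperture through the beam center receives exactly
  half the power.
* **Tester jitter**: i.i.d. Gaussian or random-walk positional noise in mm,
  standing in for handheld aiming; the mounted stimulator is the `none`
  model. The contrast reproduces the qualitative delivery-stability result:
  less jitter, higher SNR, on every seeded replicate.
* **Virtual paw**: reflectance baseline 100 mV, withdrawal drop 5 mV over a
  10 ms linear transient at the ground-truth latency, optional linear drift
  and Gaussian noise. The transient duration is a simulator choice (real
  transients are visible but not parameterized anywhere); 10 ms is fast
  relative to the 27 ms window and slow relative to one sample.
* **Key points**: six body parts at 30 fps on a 640 × 480 frame, image
  convention (origin top-left, y down), crosshair at frame center. Per-frame
  i.i.d. coordinate noise defaults to SD 3.33 px, matching the pose
  network's test error for the target hind paw. Motion alternates
  stationary bouts with instantaneous relocations (bout length 4 s by
  default) — a deliberate caricature of a resting mouse that makes
  settle-timer semantics exactly testable.

What the simulator does *not* emulate: skin optics and scattering, thermal
transport (thermal trials are modeled directly as latency distributions with
a 20 s cutoff), real paw kinematics beyond a linear transient, correlated
pose-estimation error, and posture-dependent withdrawal. Passing tests show
the algorithms are correct against the stated signal model, not that the
signal model captures every property of real recordings.

## Aiming controller

A discrete-time proportional controller runs at the 33 ms frame interval:
the commanded velocity is `gain × error`, clamped per axis at `max_speed`,
and directed to reduce the error; proportionality slows the approach near
the target, which is what prevents overshoot. For any gain in (0, 1] against
the ideal linear plant the per-axis error decays geometrically without sign
flips; at gain 0.5, a 96 px error enters the 3 px deadband in exactly
5 steps (96→48→24→12→6→3).

Choices where the design was genuinely open:

* *Deadband metric.* "Within 3 px" is read per-axis (`max(|dx|, |dy|) ≤ 3`),
  configurable to Euclidean. Per-axis matches independent x/y actuators.
* *Settle semantics.* Stimulation requires an uninterrupted in-deadband span
  of at least the settle period (2 s default). Any excursion or
  target-lost frame *resets* (does not pause) the timer — aiming is
  re-initiated and the timer restarted.
* *Error filtering.* The tracked target position is trailing-averaged over
  15 frames (0.5 s) before the deadband comparison. Raw per-frame pose
  estimates carry noise comparable to the 3 px tolerance, so an unfiltered
  deadband test would chatter and the settle timer could never complete;
  averaging a stationary target's estimate restores the intended semantics
  while leaving noiseless analyses (convergence, timer arithmetic)
  untouched. Width 1 disables filtering.
* *Confidence gating.* Key points below confidence 0.5 are target-lost: the
  actuator holds, the settle timer resets, the give-up clock keeps running.
* *Gain and clamp defaults* (0.5, 50 px/step) are exposed configuration, not
  inferred constants.

A give-up timer (30 s default) abandons an animal that never settles;
`run_trial()` then records a skipped trial with no stimulus. In closed loop,
the stimulus duration equals `min(latency + emission lag, cutoff)`, where
the emission lag is the persistence duration — a tested invariant.

## Sessions

`run_session()` interleaves animals: each round visits every animal in a
seeded random permutation, and the scheduler never re-stimulates an animal
before its inter-stimulus interval (waiting explicitly when interleaving
alone does not cover it). The simulated clock advances through aiming,
stimulation and a fixed enclosure-to-enclosure move time; record timestamps
derive from a fixed epoch plus that clock, so identical seeds yield
byte-identical logs. The session log is append-only delimited text with a
fixed 14-column schema; every row carries the trial seed and a hash of the
resolved configuration.

## Analyses

* **SNR** is `10·log10(mean²/SD²)` dB (sample SD); **CV** is `SD/mean`.
* **Bland–Altman**: differences (method 1 − method 2) against averages;
  one-sample t test of the mean difference (fixed bias); OLS of difference
  on average with a t test of the slope (proportional bias) and a t-based
  95 % prediction band; the line can be evaluated at query averages to
  express a proportional bias in ms at short and long latencies.
* **Fast/slow classification** splits latencies at 75 ms; "fast" is strictly
  below, so an exactly-75 ms latency is classed slow (the boundary rule must
  land somewhere; the strict reading of "fast < 75 ms" puts it on the slow
  side). Group proportions feed a Pearson chi-square *without* continuity
  correction; with an r × c table larger than 2 × 2 the correction question
  does not arise, and for 2 × 2 the uncorrected statistic is the
  conventional choice at these trial counts. Tables with an empty class are
  flagged before testing.
* **Power-law fits** are OLS in log10–log10 space (`a = 10^intercept`,
  `b = slope`) — linear regressions on log axes. On noiseless power-law
  data the recovery is exact to numerical precision.
* **Psychometric threshold**: logistic in log intensity by maximum
  likelihood; threshold is the intensity at fitted p = 0.5
  (`exp(−β₀/β₁)`). The logistic link is a choice — the underlying sigmoid is
  shown but never named in the source material; log-intensity symmetry makes
  the step-data threshold land at the geometric midpoint of the bracketing
  intensities. All-0/all-1 outcome sets leave the threshold undefined
  (flagged), and complete separation is flagged while still reporting the
  midpoint-consistent estimate.
* **Distribution comparison**: pooled-trial two-sample Kolmogorov–Smirnov
  plus intra-unit CVs compared by two-sample t test; units with fewer than
  2 trials are excluded with a warning.
* **Behavior–latency association**: logistic (occurrence flag) or linear
  (duration) regression on latency, with a case-resampling bootstrap
  (2000 replicates, seeded) for the slope CI. Under complete separation the
  Wald p is unreliable and reported as `NA`; the bootstrap CI carries the
  inference.

## Numerical and testing choices

Floating-point timer accumulation (60 × 33.3̅ ms ≠ 2000 ms exactly) is
absorbed by a 1 µs tolerance on timer comparisons. Sample-time comparisons
use a relative epsilon of 10⁻⁶ of the sample interval. The streaming
detector's incremental window sum and the offline cumulative-sum smoothing
agree to within ~10⁻¹² mV, far below any decision margin in practice.

Test problem sizes are the package's own choices: 1,000 seeded trials for
the streaming/offline equivalence, 200 seeds for psychometric-threshold
recovery and for the permuted-label false-positive rate, 20 seeded
replicates for the jitter/SNR ordering, 100 trials per noise level for the
monotone-degradation check, and short (0.8–2 s) cutoffs wherever the
detection logic, not the trial duration, is under test.

## Limitations

The simulator's noise models are i.i.d. Gaussian; real photodetector noise
has structure (mains pickup, breathing artifacts) that the 27 ms window and
persistence rule are designed to reject but that is not reproduced here.
The aiming plant is an ideal velocity follower with no actuator latency,
backlash or inertia. Pose-estimation error is modeled as unbiased per-frame
noise, whereas real networks err with spatial structure. No mixed-effects
modeling or multiplicity correction is applied beyond reporting raw p
values. Thermal physics is not modeled: radiant-heat trials are represented
only by their latency distribution and cutoff.
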