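---
title: "Methods: gaze reconstruction and saccade analysis in freely moving mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze reconstruction and saccade analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousegaze)
```

## The problem

A mouse pursuing a cricket moves its head continuously while its eyes
counter-rotate to stabilize the retinal image (the vestibulo-ocular reflex,
VOR), interleaved with rapid non-compensatory movements that shift gaze to
a new position. Quantifying this requires fusing three instruments that
share no clock and no coordinate frame: two head-mounted eye cameras
(pupil edge landmarks), an overhead camera (head and cricket landmarks),
and an inertial measurement unit (IMU). `mousegaze` turns these raw tables
into calibrated eye angles, head pose, behavioral epochs, reconstructed
gaze, and the summary statistics of head–eye coordination. Because no
recorded data ships with the package, a synthetic-session generator with
complete ground truth stands in for every validation.

## Eye-camera calibration from pupil ellipticity

A camera strapped to the head cannot be calibrated by asking the animal to
fixate targets. Instead the package uses the geometry of the spherical
eye: when the eye points along the camera axis the pupil images as a
circle; rotated by $\theta$ away from the axis it images as an ellipse
with ellipticity (minor/major ratio) $e = \cos\theta$, displaced from the
camera-axis center $c$ by $|p - c| = R\sin\theta$, where $p$ is the pupil
center and $R$ the scale factor converting pixels to rotation. Two facts
make this solvable from passive observation:

1. the major axis of the imaged pupil is perpendicular to $p - c$, so each
   sufficiently elliptical frame yields a linear constraint
   $m_i \cdot c = m_i \cdot p_i$ on $c$ (solved by least squares, with the
   condition number of the stacked constraints checked so that sessions
   with near-parallel major axes are rejected rather than silently
   extrapolated);
2. eliminating $\theta$ gives $|p_i - c| = R\sqrt{1 - e_i^2}$, so $R$ is a
   least-squares slope through the origin.

Pupil ellipses are fit to the 8 tracked edge points by direct algebraic
conic least squares with the ellipse constraint (the Fitzgibbon method in
its numerically stable block form), after centering and scaling the points
for conditioning. The fit is closed-form and deterministic; frames with
fewer than 5 confident points, collinear points, or a hyperbolic solution
are flagged invalid and masked downstream.

Angles are recovered with $\theta_h = \mathrm{asin}((p_x - c_x)/R)$ — the
exact inverse under the stated model rather than a small-angle linear map.
Displacements numerically outside the model ($|p-c|>R$) are clipped to
±90° and flagged. Central eye position (0°) is defined per eye as the mean
pupil location over the recording.

**Frame selection.** "Significant ellipticity" for the center step
defaults to $e \le 0.99$ (≈ 8° off axis). The scale step is stricter by
default ($e \le 0.9$, ≈ 26° off axis, falling back to the permissive cut
below 50 frames): near circularity $\sqrt{1-e^2}$ has divergent
sensitivity to landmark noise, and because a session's eye positions
concentrate at small eccentricities, weakly elliptical frames dominate the
regression and bias the slope low. The center estimate is insensitive to
this and keeps the permissive cut. Relatedly, the synthetic eye camera
renders the pupil at 30 px radius against a 60 px rotation radius — the
approximate anatomical ratio of mouse pupil to eyeball radius — because an
unrealistically small pupil makes fitted ellipticity noise-dominated.

**Measurement-error estimate.** With no ground truth for eye position, an
upper bound is computed from stability when the animal is still (speed
< 1 cm/s, frame-to-frame head rotation < 1°). The default estimator is the
standard deviation of frame-to-frame differences divided by $\sqrt 2$
(unbiased for iid noise on a constant signal); a windowed position-sd
variant is also exposed, since the verbal definition admits both readings.

## Head pose, target geometry, inertial channels

The 8 overhead head points are reduced to a rigid template by generalized
Procrustes alignment (rotation + translation only — the constellation is
rigid, so no scaling), iterated to $10^{-6}$ convergence and oriented so
the head-center → nose line lies along +x. Each frame is then fit by
closed-form weighted 2-D rigid least squares (the cross-covariance
$\mathrm{atan2}$ solution), weights taken from landmark confidence
(threshold 0.9, below which a point gets weight 0 — the trackers' own
convention for unreliable points). Yaw therefore equals head direction;
the reported position is the posed head-center point. The test suite
verifies the closed form against a dense 0.01°-step rotation search.

Speed is frame-to-frame displacement × rate, median filtered over 500 ms.
Cricket geometry: distance $D$ from the head center, azimuth $A$ = wrapped
difference between the bearing to the cricket and head yaw (0 = head
pointing at the cricket; positive = cricket to the animal's right — the
polarity is a convention the source experiments never state, so it is
configurable), and range rate = central-difference $\dot D$ smoothed with
the same 500 ms median filter as speed (the smoothing used for the closing
criterion is another unstated detail; sharing the speed filter keeps the
three approach criteria on an equal footing).

IMU accelerometer channels are median filtered over 266.7 ms to remove
transients and converted to m/s²; tilt follows from gravity as
$P = \mathrm{asin}(a_{fwd}/g)$ (nose-up positive) and roll analogously,
with values beyond gravity clipped and flagged. The standard gravity-tilt
extraction is assumed since no explicit formula is stated in the source
methods. Gyroscope channels are converted to rad/s and used unfiltered.
The head measurement error is the RMS per-frame difference between
landmark-yaw changes and integrated gyroscope yaw rate — an upper bound
that pools both instruments' errors.

## Timebase

All channels are linearly interpolated to one uniform 60 Hz grid covering
the overlap of every stream. Angle channels are unwrapped before
interpolation and re-wrapped to (−180°, 180°] after, so a yaw trace
crossing the seam never yields a spurious 360° step. No extrapolation:
output samples outside a source's own range are masked (NA), and masks
propagate through every downstream operation. Median-filter windows are
converted to the nearest odd sample count (500 ms @ 60 Hz → 31 samples;
266.7 ms @ 50 Hz → 13), with clipped windows at series ends and NA-aware
medians inside.

## Epochs

Moving = median-filtered speed strictly above 1 cm/s. Approach = the
per-sample conjunction speed > 1 cm/s, |A| < 45°, range rate < −10 cm/s,
with all boundary comparisons strict, as printed. Contiguous runs become
half-open `[start, end)` intervals. Whether the source analysis bridged
brief gaps or dropped very short bouts is not stated; the defaults bridge
gaps ≤ 100 ms and drop bouts < 250 ms (about the shortest pursuit movement
a mouse can plausibly execute), and both default to off (0) in every
ground-truth comparison in the tests, where the raw conjunction is the
defined quantity.

## Gaze, saccades, fixations

Vergence $V = \theta_R - \theta_L$ (negative = converged), mean eye
$E = (\theta_R + \theta_L)/2$, gaze $G = H + E$ computed on the unwrapped
line. Gaze velocity is the central difference × rate — symmetric, so a
single-frame step of 6° at 60 Hz reads 180°/s spread over the two
neighbouring samples, which is how the ±180°/s classification threshold is
meant to be read at this frame rate. Samples with $|\dot G|$ strictly
above 180°/s are saccadic, the rest compensatory. Because the central
difference smears one-frame steps, saccadic runs separated by a single
compensatory sample are merged (configurable); fixations are maximal
compensatory runs of at least 50 ms (threshold configurable; only the
±180°/s value is prescribed). Saccade amplitude is the gaze change from
the sample before onset to the run's last sample. Stabilization is
quantified as the RMS deviation of a channel about its within-fixation
mean, reported per fixation with the distribution median.

## Statistics

Lagged cross-correlations are Pearson correlations at integer-sample lags,
computed within mask-contiguous segments and combined across segments by
sample-count weighting — correlations are never computed across an epoch
boundary, so approach and non-approach regimes cannot mix. Positive lag
means the second series follows the first. Per-lag normalization uses each
lag's own segment statistics (the source normalization is unstated).
Differencing modes (`diff_a`, `diff_b`, `diff_both`) are applied per
segment before correlating; both the position and the differenced variants
are exposed because the source figures are ambiguous about which was
plotted. Saccade-triggered averages extract windows around onsets (with an
optional absolute-value transform for azimuth traces) and report mean ±
sem per offset. Pre/post-saccade targeting samples |head azimuth| and
|gaze azimuth| at a configurable offset before and after each onset
(default 250 ms — the source states no offset). The pitch–vergence
relationship is an ordinary least-squares line with Pearson r.

## The synthetic generator

`sim_params()` holds the study conditions; defaults were fixed once, from
the structure the analysis assumes plus oculomotor common sense, and are
exercised unchanged by the tests:

- **Arena and behavior.** 45 × 38 cm arena. Exploration (speed
  OU process, mean 6 cm/s, sd 3, τ = 1 s; slow-heading turn-rate OU sd
  6°/s, τ = 0.7 s) alternates with pursuit (exponential bout schedule,
  mean 8 s; speed mean 22 cm/s so the −10 cm/s closing criterion is met
  with margin; proportional steering toward the cricket at 8 /s capped at
  250°/s). The cricket is piecewise-stationary, relocating on capture
  (within 2 cm) or as a slow Poisson process (0.02 /s). Near a wall the
  heading is steered back toward the interior only while it points
  strongly outward, capped at 120°/s, without disturbing the exploratory
  turn-rate state — uncapped wall avoidance would inject large artificial
  turns.
- **Head.** Yaw = slow body heading + a fast scanning oscillation (OU,
  sd 14°, τ = 0.08 s). This decomposition is deliberate: head-mounted
  recordings show large rapid yaw oscillations superimposed on the
  locomotor heading, and it decouples the variance of frame-to-frame yaw
  (which drives the compensatory correlation) from the slow reorientation
  that triggers saccades. Pitch is mean-reverting (τ = 0.7 s) with sd 10°
  while exploring and 3° during approach — pitch, unlike yaw, is
  stabilized during pursuit.
- **Eyes.** Between saccades the mean eye integrates $-g\,\Delta H$ with
  VOR gain $g = 1$. A recentering saccade resets the eye linearly to 0
  over 4 frames (≈ 67 ms, a realistic gaze-shift duration at 60 Hz). The
  trigger fires when the eye's eccentricity *relative to the slow heading
  trend* exceeds 32° while the eye itself is deviated by at least 45% of
  the trigger. Triggering on raw instantaneous eye position is
  structurally wrong here: the fast yaw oscillation is VOR-imaged onto the
  eye, so a reset launched at an oscillation extreme is immediately undone
  by the oscillation's own mean reversion, producing trains of spurious
  saccades (several per second) that no mouse makes and that destroy the
  compensatory correlation structure. Gating on the trend restricts
  saccades to genuine reorientations — head turns — while the reset still
  takes the eye to 0, so gaze and head agree immediately after a saccade.
  Vergence follows pitch with slope −0.5 plus 1° of variability; vertical
  eye position is a small OU process (sd 3°, τ = 0.5 s).
- **Noise.** 0.5° iid Gaussian on exported angle channels only (eye
  angles, yaw, pitch) — the magnitude of the tracking-error upper bound
  the error estimators are designed to report; positions are exported
  clean by default so that epoch ground truth is exact. Pixel noise on
  pupil edge points and voltage noise on IMU channels are export options.
  Sub-seeds are split from the master seed per subsystem (behavior, eyes,
  measurement noise, export), so the whole session is reproducible
  bit-for-bit from one integer.

Ground truth records every saccade onset/offset and amplitude, the
fixation partition, and approach intervals derived by applying the epoch
criteria to the noiseless channels, so recovery can be scored exactly.

**What the generator does not emulate.** Landmark detector failure modes
(occlusion, blinks, confidence collapse), torsional eye rotation,
pupil-size changes, cricket locomotion beyond piecewise relocation,
video-level artifacts, and any coupling between eye movements and visual
content. Passing tests therefore certify the estimators and the event
logic under the stated statistical structure — not robustness to every
failure mode of real video tracking.

## Numerical choices and degenerate inputs

- Ties: every threshold comparison is strict (speed exactly 1 cm/s is
  stationary; gaze velocity exactly 180°/s is compensatory).
- Wrapping: internal angle series stay unwrapped; wrapping to
  (−180°, 180°] happens at export and comparison points.
- Invalid data: masks (NA) propagate; estimators that would average over
  an empty mask raise errors rather than returning NaN.
- The rigid fit requires ≥ 2 usable points per frame; frames below that
  are invalid, not extrapolated.
- Ellipse fits centre and scale points before solving; the camera-center
  solve rejects constraint sets with condition number above $10^6$.
- Test problem sizes: calibration round trips use 2000 frames; oracle
  equivalence 200 random poses; session-level checks use 600 s (default)
  and 1200 s (fixation medians and saccade-targeting, where ≥ 500 events
  are wanted) at 60 Hz.

## Limitations

Vertical gaze is carried through calibration but not segmented; torsion is
ignored; the approach detector encodes the published criteria rather than
learning them; inferential statistics (paired tests and the like) are out
of scope — the package produces the distributions and medians on which
such tests would run. The headline medians of the original recordings
(fixation duration, RMS stabilization) are statistics of those particular
sessions; the package reproduces the *procedures* and verifies them
against synthetic ground truth, not those numbers.
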