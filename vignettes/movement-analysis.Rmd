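---
title: "Quantifying infant general movements: joint-angle cosine similarity, autocorrelation and OKS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infant general movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmscreen)
```

## The problem

Infant general movements (GMs) in the writhing stage carry prognostic
information about cerebral palsy risk: cramped-synchronized (CS) GMs --
rigid, stereotyped movements in which limbs and trunk contract and relax
almost simultaneously, biased toward extension -- are a high-risk pattern,
while normal writhing GMs are variable and irregular. Scoring GMs requires
certified observers, which limits screening. This package implements the
quantitative half of an automated alternative: given per-frame 2D pose
keypoints (produced upstream by any pose-estimation model), it derives
interpretable movement features and group statistics that separate normal
from CS movement, and it scores the keypoint detector itself against
ground-truth annotations.

Two independent measurement layers are covered:

1. **Pose accuracy** (`oks_single()`, `evaluate_model()`): the object
   keypoint similarity, \(\mathrm{OKS} = \exp(-d^2 / (s^2 k^2))\), where
   \(d\) is the Euclidean pixel distance between a predicted and a
   ground-truth keypoint, \(s\) a scale constant and \(k\) a per-keypoint
   fall-off constant.
2. **Movement analysis** (`angle_timeseries()`,
   `normalized_autocorrelation()`, `ttest_by_joint_lag()`): joint angles as
   cosine similarities, their autocorrelation over a lag grid in seconds,
   and per-joint, per-lag two-sample t-tests between labelled cohorts.

## Joint angles as cosine similarity

Each of the eight joints (elbows, shoulders, hips, knees; both sides) is
represented by two limb-segment vectors rooted at the anchor keypoint --
for the left elbow, elbow-to-shoulder and elbow-to-wrist
(`canonical_anchors()`). The per-frame signal is
\[
d_{\cos}(A, B) = \frac{A \cdot B}{\lVert A\rVert\,\lVert B\rVert} \in [-1, 1],
\]
so +1 means a fully flexed joint, 0 a right angle and -1 full extension.
Cosine similarity is invariant to translation, rotation and uniform scaling
of the image coordinates, which makes the signal robust to camera placement;
it deliberately discards the rotation *direction*, so left/right mirroring
does not change it. Values are clamped to \([-1, 1]\) after floating-point
evaluation so downstream range invariants hold exactly.

The shoulder and hip anchors pair each joint with its two anatomically
adjacent keypoints (shoulder: elbow and hip; hip: knee and shoulder). These
pairings are isolated in `canonical_anchors()` so a different convention is
a one-line change.

Missing data policy: frames where any involved keypoint has confidence
below `min_confidence` (default 0), or where two keypoints coincide (a
zero-length segment), are marked missing; interior missing runs of at most
`max_gap` frames (default 5, i.e. 1/6 s at 30 fps) are linearly
interpolated, longer runs stay missing and are simply excluded from the
autocorrelation sums. The defaults are deliberately permissive because
ground-truth and synthetic data carry full confidence; real pose-model
output should set `min_confidence` to the model's usable-confidence
threshold.

## Normalized autocorrelation

Stereotyped movement is repetitive, hence predictable from its own past.
The feature is the sample autocorrelation at lag \(k\) frames:
\[
r(k) = \frac{\sum_{t=1}^{T-k} (y_t - \bar y)(y_{t+k} - \bar y)}
            {\sum_{t=1}^{T} (y_t - \bar y)^2},
\]
with \(\bar y\) the full-series mean. The summation runs to \(T - k\) so
that every term is defined; with the full-series denominator this estimator
satisfies \(|r(k)| \le 1\) (Cauchy-Schwarz) and \(r(0) = 1\) exactly. It is
computed on the full recording, not on windows. Lags are specified in
seconds and converted with `round(lag * fps)` (half away from zero); the
default grid is 1, 2, 3, 5, 7, 11 and 13 s, chosen to span short-range
periodicity and long-range stereotypy while staying well below typical
recording lengths (about 180 s, so even the 13 s lag leaves over 90% of the
sample pairs).

## Group comparison

For cohorts labelled normal and cramped-synchronized, each (joint, lag)
cell is tested with an independent two-sample t-test on the per-subject
\(r\) values. The default is the pooled-variance Student test with
\(n_1 + n_2 - 2\) degrees of freedom (Welch is available via
`var_equal = FALSE`); with the typical pilot group sizes of 5 vs 5 this
gives df = 8. The t statistic is signed normal-minus-CS, so stereotypy
appears as negative t. No multiple-testing correction is applied by
default -- the per-cell \(\alpha = 0.05\) flagging mirrors how such feature
grids are conventionally reported; `stats::p.adjust()` can be applied to
the raw `p` column when stricter control is wanted. An omnibus per-lag
MANOVA (Wilks' lambda) over a joint subset is provided by
`manova_across_joints()`; it requires strictly more residual degrees of
freedom than response columns, so with 10 subjects the response set must be
pruned (e.g. the four lower-limb joints).

`summarize_comparison()` renders the grid in the conventional `"t (p)"`
cell format with both numbers rounded to two decimals; raw values stay in
the machine-readable table. Note that a p-value recomputed from a t
statistic that was itself rounded to two decimals can differ from a printed
two-decimal p by about 0.01 near rounding boundaries.

## The synthetic cohort generator

Clinical GMA videos are private, so the package ships a generator whose
*statistical structure* -- not biomechanical detail -- matches what the
analysis assumes. Design choices, in the package's own terms:

* **Normal class**: each joint follows a stationary Ornstein-Uhlenbeck
  (mean-reverting colored-noise) process with stationary sd
  `process_sd = 0.25` cosine units and correlation time
  \(1/(2\pi \cdot \texttt{smoothness\_bandwidth})\) (default 0.23 Hz,
  about 0.7 s), sharing a weak common component
  (`inter_limb_phase_coupling = 0.15`) across joints. Upper limbs get twice
  the bandwidth, reflecting their larger effective freedom. The resulting
  autocorrelation decays to near zero within 2-3 s -- irregular movement.
* **CS class**: the lower limbs couple strongly
  (`inter_limb_phase_coupling = 0.95`) to a shared stereotyped drive:
  a flexion-extension oscillation (period 3 s, amplitude 0.22), a slow
  tonus modulation (75 s sinusoid of amplitude 0.5 plus an
  Ornstein-Uhlenbeck drift, sd 0.25, correlation time 12 s) and a constant
  extension bias of -0.35. The slow modulation is what produces the
  empirically expected signature: autocorrelation that stays high and
  tapers gradually across the whole 1-13 s lag range rather than
  oscillating with the fast period. The upper limbs couple only to the
  fast oscillation, at the normal-class coupling (0.15): arms join the
  synchronized bursts, but their slow posture wanders freely. This is the
  generator's expression of the clinical observation that upper limbs move
  with more freedom, and it makes upper-limb features distributionally
  indistinguishable from normal -- the generator reproduces a
  lower-limbs-only significance pattern by construction.
* The oscillation period (3 s), slow-modulation scale and all amplitudes
  are free choices -- no quantitative movement-frequency data exist for CS
  GMs in the writhing stage -- fixed once at values that give per-cell
  separations (|t| roughly 5 to 20 at lags 5-11 s for 5 vs 5 cohorts) on the
  same order as, and deliberately somewhat stronger than, the low-teens
  pilot cohorts this analysis is aimed at, so that the class contrast is a
  stable property of the generator rather than a coin flip at these small
  group sizes.
* Recording length defaults to 180 s at 30 fps, matching the typical
  clinical recording duration (about 179 +/- 45 s; see
  `video_frame_stats()`).
* `generate_cohort()` draws per-subject seeds from a master seed and
  jitters period and amplitude by +/-10% per subject; everything is a pure
  function of the master seed, so cohorts are bit-reproducible.
* Measurement noise: white noise of sd 0.04 on the angle scale, plus
  `perturb_keypoints()` for pixel-level Gaussian jitter on the keypoints
  themselves (displacement distances are then Rayleigh, which gives a
  closed-form expected OKS, \(E[\mathrm{OKS}] = 1/(1 + 2\sigma^2/(s^2k^2))\),
  used in validation).

The forward-kinematic skeleton (`angles_to_keypoints()`) is planar with a
fixed torso and head: shoulders and hips sit at constant pixel positions
and limb keypoints are placed by rotating the torso-reference direction by
\(\arccos\) of the requested angle value. It guarantees the round trip
angles -> keypoints -> `angle_timeseries()` is the identity to within
floating-point error, and all keypoints stay inside the configured image.
What the generator does *not* emulate: torso motion, occlusion,
perspective, depth-dependent scale changes, pose-model failure modes
(switched left/right limbs, dropped detections in bursts), or
poor-repertoire GMs. Passing tests on synthetic cohorts therefore
demonstrate the correctness and statistical behaviour of the measurement
pipeline under its stated assumptions, not clinical performance on real
videos.

## OKS conventions and caveats

Two formula variants are implemented: the `"paper"` variant
\(\exp(-d^2/(s^2k^2))\) (default) and the `"coco_standard"` variant
\(\exp(-d^2/(2 s^2 k^2))\) with the ecosystem's conventional factor 2.
With the tight reference constants (\(s = 1\), \(k = 0.001\)) and \(d\) in
raw pixels the score underflows for any visible displacement, so the units
of \(d\) under those constants are effectively a free convention; the
implementation keeps distances in raw pixels by default and offers
`normalize = "diagonal"` (divide by the image diagonal) plus fully
configurable constants. Keypoints with no visible ground truth are excluded
from their per-keypoint mean and flagged, never scored zero. Aggregation
reports both the sample (n-1) and population (n) standard-deviation
conventions, since published per-keypoint tables mix the two.

Model-vs-model comparison (`compare_models()`) is a paired t-test across
the 17 per-keypoint means (df = 16): when only per-keypoint summaries are
available, pairing on keypoints is the only reproducible choice.

## Numerical choices and degenerate inputs

* Cosine values and OKS inputs are validated; zero-length limb vectors
  raise a degenerate-geometry error in scalar use and become missing
  frames in series extraction.
* Constant angle series (zero autocorrelation denominator) raise an error
  rather than returning NaN.
* Exactly constant groups with unequal means get an infinite-t sentinel
  with p = 0; equal constant groups get t = 0, p = 1.
* Lag-to-frame conversion rounds half away from zero so a 0.05 s lag at
  30 fps maps to 2 frames, not 1 (base R's `round()` rounds half to even).
* All simulation entry points restore the caller's RNG state.

## Problem sizes used in validation

The shipped validation suite exercises: autocorrelation against a
brute-force summation oracle on series up to 2000 frames (agreement to
1e-12); 50 independent 5-vs-5 synthetic cohorts at full 180 s length for
the class-separation property; 2000 null simulations for type-I error
calibration of the per-cell t-test; 2000-frame sequences for the
OKS-under-jitter closed form; and exact enumeration oracles (all 252
group relabelings for the two-sample permutation check, all 2^17 sign
flips for the paired comparison). These sizes were chosen so the whole
suite completes in a couple of minutes while leaving Monte-Carlo error
well below the asserted tolerances.
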