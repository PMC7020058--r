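---
title: "Detecting bites in meal videos from pose keypoints: methods and design"
author: "bitewise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bites in meal videos from pose keypoints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitewise)
```

## The problem

Microstructural analysis of human eating quantifies *within-meal*
behaviour: when a meal starts and stops, how many bites are taken, and how
the biting rate evolves as the meal progresses.  The reference methodology
is manual annotation of meal videos — a trained annotator marks every
spoonful (food leaves the plate), bite (food enters the mouth) and food
addition, plus the meal start (first spoonful) and stop (last bite) — but
annotation takes a multiple of the meal duration per video and limits the
scale of behavioural studies.

`bitewise` implements the automatic alternative: a pose-estimation
front end (external; OpenPose-style) reduces each video frame to a small
set of 2-D keypoints — eight upper-body joints (nose, neck, shoulders,
elbows, wrists) and four mouth points (corners A/C, upper-lip mid B,
lower-lip mid D) — and this package turns those keypoint streams into a
timestamped bite log and meal-level summaries.  Everything downstream of
pose estimation is covered: feature preprocessing, a trainable two-stream
neural bite classifier, sliding-window inference, probability-signal peak
extraction, meal analytics and agreement statistics, plus a synthetic
keypoint generator so that the entire chain is testable without any video
data.

## The detector

### Feature streams

The detector's premise is that hand and mouth motion carry essentially all
of the evidence for a bite.  Two feature streams are built per frame
(`assemble_features()`):

* **body stream** (44 values): the 2-D coordinates of the 8 joints
  re-origined on the *neck*, plus all 28 pairwise inter-joint Euclidean
  distances;
* **mouth stream** (9 values): the coordinates of B, D and the *visible*
  mouth corner re-origined on the *nose*, plus their 3 pairwise distances.

Re-origining makes both streams exactly invariant to where the subject
sits in the frame.  Scale is deliberately left in pixels: the recording
geometry is fixed within a study, and distances (mouth aperture, wrist
travel) are themselves informative.  A side camera sees only one mouth
corner reliably, so `select_mouth_side()` picks the corner (A = left,
C = right) with the higher mean detection confidence over the meal, ties
going to the left.

Whether inter-point distances should be all pairwise or anchored (say,
wrist-to-nose only) is an open choice; the pairwise set is a superset of
any anchored subset and lets the classifier select what it needs, at the
cost of a wider input.  The layout is fixed and documented so results are
reproducible.

### Cleaning and smoothing

Pose estimators drop points (missed detections) and occasionally emit
spikes (a point jumps across the frame for one frame).  `clean_sequence()`
first marks as missing every point with detection confidence below
`confidence_floor` (default 0.1) and every point whose displacement from
its last accepted position exceeds `jump_fraction` (default 0.15) of the
frame diagonal — roughly 138 px at 720x576, far above genuine hand speed —
then imputes every missing value with the point's previous value (leading
gaps are back-filled from the first valid frame).  The rule is idempotent
and fails loudly if a point is never detected at all.

`smooth_sequence()` then replaces each coordinate trajectory with a cubic
smoothing spline evaluated at every frame.  The penalty is chosen per
trajectory by generalised cross-validation; a knot is placed at every
frame (`all.knots`), which matters: a restricted knot budget acts as a
low-pass filter that visibly attenuates the one-second bite gestures the
classifier must see, whereas the full basis with a GCV-chosen penalty
removes jitter while leaving gestures intact.  `spline_smoothing = 0`
requests the interpolation limit and returns the input unchanged.

### Architecture

The classifier (`train_model()`) operates on 2-s windows (50 frames at
25 fps) of the two streams and mirrors the same structure in each: two
blocks of two 1-D convolutions (ReLU, same padding) with max-pooling
after each block extract local spatio-temporal patterns, a stacked LSTM
consumes the pooled sequence and its final hidden state summarises the
window, the two stream summaries are concatenated, and a fully connected
fusion layer feeds a single sigmoid bite probability.  Training minimises
binary cross-entropy with Adam; positives are up-weighted by the
negative:positive ratio of the training corpus (roughly 2:1 in
study-scale corpora) when `class_weighting` is on.

The network is implemented directly in R on BLAS matrix operations
(im2col convolutions, batched LSTM steps), with the backward pass written
alongside each layer and verified against central finite differences in
the test suite.  The default widths — conv 16/32 filters, LSTM 32 then
16 units, fusion 32 — are intentionally small: the keypoint inputs are
low-dimensional and the configuration trains on a single CPU core in
minutes while saturating the synthetic benchmark; every width is
configurable through `model_config()` for harder corpora.

### Training clips

`extract_labeled_clips()` cuts one positive clip centred on every
annotated bite and tiles negatives every `negative_stride_s` (default
1 s) over regions whose centre is at least the window length (2 s) from
every bite, so a negative window never overlaps a gesture.  Clips that
would cross the meal boundary are dropped.  `split_clips()` holds out
`floor(0.1 N)` clips, stratified by label with largest-remainder
allocation — a 90/10 split of a 12,121-clip corpus yields exactly 1212
evaluation clips.

### Inference and peak extraction

`probability_signal()` slides the window over a whole meal with a step of
one frame and assigns each window's probability to its *centre* frame
(symmetric evidence; anchoring to the window start or end would bias
detected times by a second).  Edge frames replicate the nearest computed
value.  The batched implementation is required to equal a naive
window-at-a-time loop exactly, and is tested against one.

`extract_bites()` converts the probability signal into events in four
steps: (1) a running median (default 0.52 s, i.e. 13 frames at 25 fps;
edge frames are kept unfiltered so the filter is exactly reproducible)
suppresses isolated spikes; (2) the detection threshold is the mean plus
`threshold_k` (default 1) standard deviations of the filtered signal —
a per-meal adaptive rule with no tuned absolute threshold; (3) local
maxima above the threshold become candidates, with plateau-aware peak
finding (a maximal run of equal values strictly above both neighbours
counts as one peak at its middle frame) because a running median
frequently produces exact plateaus; (4) candidates are accepted from
highest to lowest, discarding any candidate within `min_separation_s`
(default 1 s) of an accepted bite.  Keep-highest pruning was chosen over
iterated removal of the lower member of each too-close pair: the two
rules differ on chains of close peaks, where pairwise removal lets one
strong peak cascade-eliminate neighbours that end up far from every
surviving peak.  The whole procedure commutes with increasing affine
rescaling of the signal, so it is insensitive to calibration of the
probability scale.

A constant signal has zero standard deviation and no value strictly above
its mean, hence no detections — flat-signal inputs are a tested degenerate
case, not an error.

## Meal analytics

`meal_summary()` anchors a manual meal at the first spoonful (falling
back to an explicit meal-start event, then to the first bite) and at the
last bite.  A detected log contains only bites, so detected meals are
anchored first-to-last detected bite; this is the one systematic
difference between the two sources and is recorded in the summary's
`source` field.

`segment_bite_rates()` partitions the meal duration into ten equal
segments, half-open on the right with the final segment closed, so counts
always sum to the total bites.  `fit_quadratic()` fits
$y = y_0 + a x + b x^2$ by ordinary least squares on the segment index
$x = 1..10$.  The segment *index* (not the midpoint fraction) is the
fixed convention: any affine re-parameterisation of $x$ changes the
coefficients, so the convention must be stated once and kept.  The fit is
exact on noiseless quadratic input and is tested against an explicit
normal-equations solve.

## Agreement statistics

`confusion_metrics()` computes Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$, recall, specificity, precision and
*two* F1 variants: the standard bite-class harmonic mean of precision and
recall (`f1_bite`), and the harmonic mean of recall and specificity
(`f1_rs`).  Both are reported and labelled because published clip-level
summaries in this area sometimes quote the latter: for the matrix
(tp 374, fn 27, fp 30, tn 781) the bite-class F1 is 0.929 while the
recall/specificity harmonic mean is 0.948.  No guess is made about which
a given publication intended; both numbers are always available.
Kappa above 0.80 is read as near-perfect agreement, 0.60–0.80 as
satisfactory.

`match_events()` compares two bite *event* lists under a time tolerance
(default ±1 s) by maximum-cardinality one-to-one matching, solved
greedily in time order (optimal for points on a line, and tested against
exhaustive matching).  Clip-level evaluation needs no matching step, but
event-level validation of the full pipeline does, and the tolerance is
exposed because no canonical value exists.  `correlate_measures()` is a
plain Pearson correlation with qualitative bands at $R^2 \ge$ 0.50
(medium), 0.75 (high) and 0.90 (very high).

## The synthetic meal generator

No keypoint data from real meals are shipped, so `simulate_meal()`
generates meals with the statistical and kinematic structure the detector
assumes:

* **Bite times** follow a quadratic meal-progress rate profile: the meal
  is split into ten segments, segment $x$ receives a Poisson count with
  mean $y_0 + a x + b x^2$, and times are placed uniformly within their
  segment.  The default coefficients (6.909, −0.7409, 0.0683) describe a
  decelerating-then-accelerating eater averaging about 55 bites per meal
  — denser biting at the start and end than in the middle.  Consecutive
  bites closer than a refractory gap (default 1.5 s) are re-sampled
  within their segment; the recipe is deliberately simple enough to
  re-implement independently, and the test suite does exactly that.
* **Kinematics**: every point rests at a plausible seated posture;
  around each bite the eating wrist travels plate → mouth → plate along a
  cubic ease-in/ease-out path over `gesture_duration_s` (default 1 s)
  centred on the bite, the elbow follows at reduced amplitude, and the
  mouth aperture (B–D distance) opens by `aperture_px` (default 14 px),
  both peaking exactly at the bite frame.  In the noise-free limit the
  frame of minimal wrist-nose distance within each gesture *is* the
  annotated bite frame — a tested invariant.
* **Degradations** mimic pose-estimator output: Gaussian jitter on every
  coordinate (default SD 1.5 px), per-point dropouts (confidence 0,
  default 2%), one-frame outlier spikes to a uniform in-frame position
  (default 0.5%), and a low-confidence far mouth corner, so side
  selection, cleaning and imputation all have real work to do.
* Each bite is preceded by a spoonful `spoonful_lead_s` earlier (default
  0.5 s — the hand leaves the plate about half a gesture before the
  bite), and the log carries meal-start/stop and occasional
  food-addition events.

All randomness derives from a single integer seed; identical
configurations reproduce byte-identical outputs.

What the generator does *not* emulate: chewing and drinking gestures,
posture shifts, occlusions that persist for seconds, camera motion, or
multi-person scenes.  Passing the synthetic benchmark therefore shows
that the pipeline is implemented correctly and can recover the structure
it was designed for; it does not certify performance on real video,
where the gesture vocabulary is richer and occlusion is the dominant
failure mode.

## Problem sizes and numerical choices

The package's own benchmark (also run by `scripts/acceptance.R`) uses 20
simulated meals of 240 s at 25 fps with the rate profile scaled to half
the default (about 27 bites per meal), leaving room between gestures for
negative-clip tiling at a roughly 1:5 positive:negative ratio, with
jitter 1.5 px, 2% dropout and 0.5% outliers.  Training uses the default
model configuration on 90% of the ~3400 clips; on one CPU core the whole
chain — simulation through evaluation — takes a few minutes.  On these
conditions the held-out clip kappa, the ±1 s event-level F1 against
ground truth, and the per-meal total-bite correlation all sit near their
ceilings (≥ 0.99 at seed 1).

Numerical conventions worth stating once: frames are 0-based and frame
$i$ occurs at exactly $i/\mathrm{fps}$ seconds; keypoint files render
coordinates with 17 significant digits and annotation times with six
decimals, making write–read–write round trips byte-identical; the
clip window of 2 s at 25 fps spans frames $c-25$ to $c+24$ around its
centre $c$; ties in side selection go left, ties in peak pruning go to
the earlier peak; and the degenerate cases (zero-bite logs, constant
signals, never-detected points, meals shorter than the window) each have
a defined behaviour — error or empty result — exercised by tests.

## Known limitations

* The detector learns the synthetic gesture vocabulary easily; real
  meals need real training data, and the package deliberately ships no
  pretrained weights.
* Detected meals are anchored on detected bites, so a missed first or
  last bite directly shortens the measured duration.
* Spoonfuls and food additions are manual-annotation concepts; the
  detector makes no attempt to recognise them.
* The LSTM implementation is single-threaded R; it is fast enough for
  keypoint streams (the design point), not for raw-video-scale inputs.
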