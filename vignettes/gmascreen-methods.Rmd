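---
title: "Automated General Movements screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated General Movements screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

The General Movements (GMs) Assessment scores the quality of an infant's
spontaneous movements at 9–20 weeks term-corrected age. In this window,
healthy movement is dominated by *fidgety movements* — continuous small
movements of moderate speed and variable acceleration — and their absence or
abnormality is one of the strongest early markers of cerebral palsy risk.
Expert scoring from video is accurate but scarce; `gmascreen` implements an
automated pipeline that starts from pose-estimation keypoint tables (x, y,
confidence for 18 named body points per frame, as exported by tools such as
DeepLabCut) and ends in a calibrated probability that a video shows
abnormal/absent GMs.

The pipeline has five stages, each exposed as ordinary functions:

1. **IO** — `read_keypoints()` ingests the two common keypoint CSV dialects;
   `write_feature_matrix()` / `read_feature_matrix()` store the preprocessed
   representation losslessly as text.
2. **Preprocessing** — `preprocess_video()` turns raw pixels into a
   `46 x 4500` feature-by-frame matrix in infant-normalised coordinates.
3. **Classification** — `gma_fit()` trains a causal-convolution
   clip-attention network; `predict_video()` produces calibrated
   probabilities and per-clip attention weights.
4. **Evaluation** — `run_cv()` runs repeated grouped stratified
   cross-validation; `saliency()` and `saliency_clip_analysis()` interrogate
   what the model attends to.
5. **Baselines** — `fit_baseline()` / `fit_kernel_baseline()` give the
   canonical-feature logistic-regression comparison models.

A synthetic supine-infant simulator (`simulate_video()`,
`generate_dataset()`) generates labelled keypoint data with the failure
modes of real home-recorded video, so every stage is testable without
identifiable infant videos.

## Preprocessing geometry

All geometry is expressed in image coordinates (origin top-left, y down)
and in *infant unit lengths*: the crown-to-mid-hip distance. The stages run
in a fixed order: confidence filtering → quality control → whole-body
outlier removal → per-point outlier removal → gap filling → rotation
alignment → scaling/centring → framerate normalisation → feature
extraction.

**Confidence filtering and QC.** Coordinates with pose-estimation
confidence strictly below 0.2 are treated as missing. A video passes
quality control when, averaged over frames, at least 70% of the 18 points
are labelled; `preprocess_video()` refuses failing videos unless told
otherwise, and `predict_video()` refuses them outright.

**Elliptical outlier removal.** Mislabelled points are removed in two
passes. The whole-body pass removes points outside an ellipse centred at
the torso centre (midpoint of mid-shoulder and mid-hip) with semi-axes of 3
unit lengths along the proximal–distal axis and 2 along the
medial–lateral axis — read as semi-axes because the envelope must contain
fully extended limbs. The per-point pass removes frames outside an ellipse
centred at the point's framewise median position (in torso coordinates)
with semi-axes of `k = 4` robust standard deviations (1.4826 × MAD) per
direction. The robust estimate was chosen over the raw SD so that removing
a gross outlier barely changes the envelope, making the stage
near-idempotent; a floor of 0.05 unit lengths guards perfectly still
points, and points observed in fewer than 10 frames are skipped. When a
whole dataset is available, `pointwise_stats()` pools the per-point
statistics across videos and makes the stage exactly deterministic in them.

**Gap filling.** Interior gaps of up to 5 frames are linearly
interpolated. Longer gaps (and leading/trailing gaps) are initialised by
nearest-observation interpolation and refined by a round-robin multivariate
imputer: each affected coordinate channel is regressed with ordinary least
squares (intercept included) on the other 35 channels over its observed
frames, missing frames are replaced by the prediction, and the sweep
repeats until the largest change is below 1e-3 unit lengths or 10 passes.
Observed values are never altered.

**Camera adjustment and normalisation.** Every frame is rotated about its
torso centre so the body midline (mid-shoulder → mid-hip) is vertical with
the hips below the shoulders; this removes angular camera motion exactly
when the trunk itself does not rotate. Coordinates are then divided by the
per-video *median* unit length (the median resists residual mislabels; the
source protocol does not state per-frame vs per-video normalisation) and,
by default, each frame is translated so the mid-hip sits at the origin.
Centring is not part of the stated protocol — only rotation and scaling
are — but makes coordinates pose-relative, which the saliency displacement
analysis implicitly assumes; it is configurable off
(`preprocess_config(center = FALSE)`).

**Framerate normalisation and features.** Native frame rates vary from 15
to 31 fps, so every channel is cubic-spline interpolated from its native
timestamps onto 4500 uniform timepoints (3 minutes at a nominal 25 fps).
The feature matrix stacks the 36 coordinates (x before y, in the canonical
`body_points()` order) and 10 joint angles in radians. Angles are interior
vertex angles via the arccosine of the normalised dot product; the segment
pairs (shoulder: to ipsilateral hip / to elbow; elbow: to shoulder / to
wrist; hip: to ipsilateral shoulder / to knee; knee: to hip / to heel;
ankle at the heel: to knee / to big toe) use only the landmarks the point
set provides. A zero-length segment yields π with a warning rather than an
error, since a collapsed segment is indistinguishable from a straight
joint at pixel resolution.

Two properties pin the geometry down: the full pipeline is invariant to
global similarity transforms of the raw pixels (rotation + translation +
zoom), and joint angles are unchanged whether computed before or after the
normalisation. Both are enforced by tests.

## The clip-attention classifier

Each video is represented at inference as 547 overlapping clips of
`t = 128` frames (stride 8, about 5 s at 25 fps). Clips pass through three
causal 1D convolutions along time (64 filters, kernel 3, ReLU), each
followed by batch normalisation and max pooling (window and stride 4),
shrinking the temporal axis 128 → 32 → 8 → 2. The two remaining timesteps
are concatenated into a 128-vector and mapped by a fully connected layer
(64 units, ReLU; dropout 0.5 before and after) to the clip embedding
$m_c \in \mathbb{R}^{64}$.

Clips are pooled with sigmoid attention:

$$u_c = \tanh(W m_c + b), \qquad
  \alpha_c = \frac{1}{1 + e^{-u_c^\top u}}, \qquad
  v = \frac{1}{n}\sum_{c=1}^{n} \alpha_c m_c ,$$

where the context vector $u$ and the layer parameters are learned jointly;
$\alpha_c \in [0,1]$ is the importance of clip $c$ and $v$ is the
attention-weighted *mean* of the clip embeddings. A final dropout (0.5) is
applied to $v$ only; the optional metadata branch (below) is concatenated
afterwards, and a 1-unit sigmoid layer produces the raw score.

Choices the architecture description leaves open, decided here:

* **Batch-norm placement** — after the activation (conv → ReLU → BN →
  pool); configurable in principle, the contract tests do not depend on it.
  Running statistics use momentum 0.99 and are frozen at inference.
* **Metadata shape** — the length-2 vector (z-scored age at acquisition,
  binary birth cohort) is treated as a 2-step, 1-channel sequence so the
  kernel-1, 4-filter convolution is non-degenerate, giving a 2 × 4 = 8
  vector. Age is standardized with training-split statistics. Without
  metadata the model runs in movement-only mode.
* **Label smoothing** — symmetric: targets $y' = y(1-0.1) + 0.05$, i.e.
  {0.05, 0.95}.
* **Weight initialisation** — uniform fan-in scaling with a per-fit seed.
* **Validation loss** — computed per *video* through the same all-clip
  inference path used at deployment, so early stopping tracks the
  deployable model rather than single sampled clips.

Training uses SGD with Nesterov momentum 0.9, learning rate 0.005, batch
size 8, and an l2 penalty of 0.005 on weight kernels only (not biases or
batch-norm parameters). Each epoch samples `s = 1` random clip per video
(fresh each epoch), oversamples minority-class videos ×5 — a 408/76 class
split becomes 408 vs 380 per-epoch samples — and augments each sampled
clip. Training runs to a 10000-epoch cap with early stopping: when
validation loss has not improved for 100 epochs, the parameters from the
minimum-loss epoch are retained.

The network is implemented directly in vectorized base-R linear algebra:
convolutions as im2col matrix products, with hand-derived backpropagation
through every stage (pooling argmax routing, batch-norm, attention).
Activations are stored feature-major so per-channel parameters broadcast
via column-major recycling; the gradient of every parameter block and of
the input (the saliency path) is verified against central finite
differences in the test suite.

## Augmentation

Two timeseries augmentations are applied to each training clip, in order:
magnitude scaling, then time warping. Both draw a smooth random curve: a
cubic spline through `k ~ U{3..15}` knots placed uniformly across the clip,
with knot values from N(1, 1). One curve is shared across all 46 features
per augmentation (preserving inter-limb coordination; per-feature curves
are configurable).

* **Magnitude scaling** multiplies each timeseries elementwise by the
  curve. Joint-angle rows are scaled about π/2 — deviations from a neutral
  posture are scaled, not absolute radians — and clipped back to [0, π].
* **Time warping** clamps the curve at 0.1 (keeping the implied time map
  strictly increasing), takes its cumulative sum as a distorted time grid
  rescaled to the clip length, and re-interpolates the clip back onto the
  uniform grid with shape-preserving (Fritsch–Carlson) piecewise-cubic
  interpolation. The shape-preserving form was chosen over an ordinary
  cubic spline so monotone channels stay monotone and clip endpoints are
  preserved exactly.

Augmentation is training-only; inference uses exact windows. Labels are
never touched.

## Calibration and class imbalance

Minority oversampling improves learning under the ~5:1 class imbalance but
miscalibrates raw scores. Platt scaling is fitted post hoc on the
validation videos: a logistic regression of labels on the *logit* of the
raw score (the pre-sigmoid margin — standard Platt practice; fitting on
the raw score is available as an option). The fitted transform is monotone
whenever its slope is positive, and the validation Brier score is never
worsened in the regimes the tests exercise. Predicted label is abnormal
when the calibrated probability is at least 0.5.

## Evaluation protocol

`make_splits()` draws repeated (default 25) random 70/15/15
train/validation/test splits, stratified by the binary label and grouped
by infant — both videos of an infant always share a subset. Metrics are
AUC (trapezoidal ROC over unique thresholds, identical to the rank-based
estimator and cross-checked against pROC), balanced accuracy, sensitivity,
specificity, PPV and NPV with abnormal as the positive class.

Across repeats each video lands in several test sets;
`aggregate_labels()` assigns the most frequent predicted label, breaking
ties toward abnormal — a screening-posture choice that favours negative
predictive value — alongside the median calibrated probability
(calibrated, not raw, scores are aggregated).

`saliency()` computes vanilla-gradient maps: the absolute gradient of the
raw video score with respect to every input element, summed over frames
within each clip. `saliency_clip_analysis()` compares clips at or above
the 90th percentile of total saliency with those at or below the 10th
(percentiles pooled over the videos supplied, e.g. the test set of one
repeat; ties included on both boundaries). Each clip is summarised by the
mean over frames and points of the displacement magnitude from the
per-video average position (each point's mean coordinates over all
frames), and by the mean over points of the per-point SD of displacement
over frames.

## Baseline models

Each of the 46 feature timeseries is summarised by 24 canonical features:
the 22 widely used "catch" dynamical features (distribution shape and
outlier dynamics, autocorrelation timescales, spectral summaries, symbolic
motif entropies, local forecasting error, fluctuation scaling, periodicity)
plus the raw mean and SD. No R implementation of the canonical set is
available, so the features are implemented here following their published
definitions, computed on the z-scored series, with fixed output order and
defined values on constant input. The exact feature list of the reference
tooling differs in minor numerical conventions; the baseline's role — a
fixed, deterministic summary battery — does not depend on bit-level
agreement.

Feature vectors (46 × 24 = 1104, plus age and cohort = 1106) are z-scored
with training-split statistics and fed to an l2-regularised logistic
regression (glmnet ridge path). The inverse regularisation strength is
chosen from the 7-decade grid 10^-3 … 10^3 by nested 5-fold
cross-validation on AUC inside each of 25 repeated 85/15 group-disjoint
splits (glmnet's λ corresponds to 1/(C·n)). The kernelised variant maps
standardized features through a Nystroem approximation of the RBF kernel
(100 landmark components, bandwidth 1/n_features by default; both values
are unstated in the protocol and set to the common defaults) before the
same ridge pipeline.

## The synthetic simulator

The simulator emulates the statistical structure the pipeline assumes, not
infant biomechanics:

* a supine 18-point skeleton, left/right symmetric, with crown-to-mid-hip
  distance defining the unit length;
* rigid trunk translation (shoulders and hips move together, so the
  midline angle is driven by the camera alone — this is what makes the
  camera-rotation ground truth exactly recoverable and is a deliberate
  simplification: real infants arch and roll);
* slow gross limb movements (low-passed Gaussian noise) plus a
  band-limited 0.5–3 Hz "fidgety" component of amplitude `fidgety_amp`
  unit lengths, weighted toward the lower body;
* class 1 (abnormal/absent) videos suppress (×0.1) or exaggerate (×3) the
  fidgety component, chosen at random per video, mirroring the pooling of
  absent and abnormal ratings into one screening-positive class;
* hand-held camera motion: slow bounded rotation (default ≤ 15°) and
  translation drift applied to all points, with the trajectory retained as
  ground truth;
* occlusion episodes (Poisson-arriving, tens of frames) drawing confidence
  from U(0, 0.2) so the 0.2 threshold removes them, visible frames from
  U(0.7, 1); and sparse high-confidence mislabels displaced ≥ 1.2 unit
  lengths, which only the elliptical envelopes can catch;
* metadata: acquisition age U(12, 18) weeks; preterm birth enriched in the
  abnormal class (85% vs 30%), echoing the preterm skew of abnormal
  ratings in screening cohorts.

Defaults follow the acquisition regime of home smartphone recordings:
180 s duration, integer frame rates 15–31, prevalence 76/484, and roughly
47% of infants contributing two videos. The fidgety amplitude default
(0.03 unit lengths) is a placeholder chosen for test separability — no
quantitative amplitude/frequency of real fidgety movements is claimed.

Passing tests on this generator show that the pipeline recovers the
*constructed* class signal end-to-end; they do not show clinical validity.
Real videos differ in ways the simulator does not model: non-rigid trunks,
rolling and out-of-frame movement, clothing- and skin-tone-dependent
labelling bias, correlated multi-point occlusions, and fidgety movements
whose spectral signature is only loosely band-limited.

## Desk-scale benchmark sizes

`synthetic_benchmark()` is the package's end-to-end class-recovery
experiment and the basis of the acceptance checks. Its problem sizes are
the package's own desk-scale choices: 120 balanced videos of 40 s
(resampled to 1000 frames, preserving the 25 fps temporal scale so the
fidgety band is untouched), a 500-epoch cap with patience 100, validation
clip stride 64, no oversampling (the design is balanced) and movement-only
mode — with metadata correlated to class, a zero-contrast cohort would not
be at chance, and the experiment is meant to isolate the movement pathway.
Contrast settings probe `fidgety_amp` at 0 (classes identical), 0.03 (the
generator default) and 0.12 ("strong"). The grouped stratified 70/15/15
split supplies the training and validation sets; the reported AUC is
measured on an *independently simulated* held-out cohort of 120 further
videos rather than the 18-video split-test subset, because with 18 videos
the chance-level AUC estimate has a standard deviation of roughly 0.14 —
too coarse to distinguish chance from weak signal — while 120 videos bring
it under 0.06. The split-test AUC is also returned for reference.

## Numerical choices and degenerate inputs

* Resampling uses R's `spline()` (fmm) — an interpolating cubic that
  reproduces node values exactly; the augmentation warp uses the
  shape-preserving cubic described above.
* Band-limited noise is generated by FFT masking and rescaled to the
  target SD, avoiding filter edge effects.
* The imputer solves rank-deficient regressions by QR with zeroed
  aliased coefficients, so perfectly collinear channels are handled.
* Batch-norm variance is floored at 0; attention logits pass through a
  numerically plain sigmoid (embedding norms keep them in range); scores
  are clamped to [1e-12, 1 - 1e-12] inside log-losses.
* Degenerate guards: zero unit length, zero-length midline, channels with
  no observations, single-class training or validation sets, and constant
  Platt scores all raise (or warn with) explicit messages.

## Known limitations

* The network trains on CPU via BLAS matmuls; it is intended for
  hundreds of videos, not thousands, and has no GPU path.
* The simulator's rigid trunk makes rotation recovery exact; pipelines
  facing rolling infants will see residual midline error that this test
  regime cannot reveal.
* The 22 dynamical baseline features follow published definitions but are
  not bit-compatible with any specific reference implementation.
* Calibration quality depends on the validation set size; with very few
  validation videos the Platt fit is noisy, and `fit_platt()` only warns
  (not errors) on near-degenerate inputs.
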