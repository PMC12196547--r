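---
title: "Dual-view gait screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view gait screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitscreen)
```

`gaitscreen` implements a complete computational pipeline for screening
Parkinson's disease (PD) from dual-view gait video: two synchronized
cameras (one frontal, one lateral) film a person walking, an upstream
pose estimator turns each video into per-frame skeletal keypoints, and
the package segments, normalizes and classifies the resulting keypoint
sequences. This vignette describes each stage's model and assumptions,
the tunable parameters, the numerical choices, and what the synthetic
validation does and does not establish.

## From keypoints to single steps

**Input.** Per-view keypoint files carry one row per frame with 17
joints in COCO ordering, each an (x, y, confidence) triple in pixels at
30 fps. The four face joints with no locomotor content (eyes, ears) are
dropped, leaving 13 joints; with three channels each this gives the
fixed 39-dimensional per-frame feature vector. The two views are assumed
synchronized at acquisition; residual length mismatches are resolved by
truncation to the common length, and no resynchronization is attempted.

**Single-step segmentation.** A single step runs from one right-foot
landing to the next left-foot landing. Landings are local minima of the
lateral-view ankle elevation (under the image convention, pixel y grows
downward, so elevation is `-y`; a `y_axis` flag covers the opposite
convention). The elevation series is first smoothed with a
Savitzky–Golay (SG) filter — window 45 frames, polynomial order 6 — a
local least-squares smoother chosen because it suppresses pose-estimator
jitter while preserving extremum *positions*. Near the series edges the
window is truncated and refitted rather than padded, so no data are
invented where an event might sit; positions are rescaled to [-1, 1]
inside each window so the order-6 Vandermonde system stays
well-conditioned.

Minima are located by a sliding-window peak search on the negated
series: a candidate must be the maximum of its 30-frame neighbourhood
and carry a peak prominence above a threshold; retained candidates must
be at least 30 frames apart, with conflicts resolved in favour of the
deeper landing (ties keep the earlier frame). The prominence threshold
is mean body height / 20, where body height is the per-frame distance
between the head keypoint and the ankle midpoint averaged over the
recording — tying the threshold to apparent body size makes the detector
invariant to camera distance. Each retained minimum is then relocalized
by the vertex of a least-squares parabola fitted over its surrounding
half-window: the raw argmin rides on whatever noise the SG stage leaves
behind (roughly one frame of jitter per pixel of noise), whereas the
vertex averages the whole valley. The shift is capped at 3 frames,
skipped at series edges, and discarded if it would violate the
minimum-separation contract.

Stationary spans — the person standing at the turn-around points — are
excluded: a frame is stationary when the windowed peak-to-trough
amplitude of *both* ankles' smoothed elevation falls below the
prominence threshold. The window for this test spans
`3 * min_separation + 1` frames (91 by default). A shorter window
cannot work in principle: the two ankles oscillate in antiphase, so at
every landing one foot is at its minimum and the other at its maximum,
and both curves are locally flat; only a window comparable to a full
step sees the true movement amplitude. Steps intersecting stationary
spans are dropped, as are steps shorter than 20 or longer than 120
frames (a missed landing would otherwise create a multi-cycle
"step"; typical steps run near 50 frames). The same frame boundaries
are applied to the temporally aligned frontal view.

## Normalization

Each segmented step is rescaled by its own vertical extent:
`x' = (x - mean(x)) / (max(y) - min(y))`,
`y' = (y - min(y)) / (max(y) - min(y))`, with statistics over all
frames and joints of the step. Both axes share the divisor, so aspect
ratio is preserved, and the result is invariant to image translation
and uniform scaling — the property that lets recordings taken at 2 m
and 4 m camera distances share one model. Confidence values are not
touched by this geometric step. Steps are then brought to exactly 50
frames by piecewise-linear interpolation at uniformly spaced positions
including both endpoints; resampling is used in both directions (a
`trim` option reproduces plain truncation) because it is deterministic
and preserves endpoints and monotonicity. Finally the whole dataset is
z-scored per feature column (39 columns, per view), with the statistics
fitted on the *training folds only* and stored for reuse at validation
and inference time — computing them on the full dataset would leak
validation information into training. Zero-variance columns pass
through centred with a warning.

## The dual-stream fusion network

Each step sample is a pair of 50 × 39 matrices (frontal, lateral). Two
weight-independent streams process them through four layers that
alternate two temporal-mixing mechanisms:

* **Self-attention blocks** (layers 1 and 3): multi-head scaled
  dot-product attention (3 heads, `softmax(QK'/sqrt(d_k))V`), residual
  connection, layer normalization, a SiLU feed-forward network of width
  64, and a second residual + normalization (post-norm).
* **State-space blocks** (layers 2 and 4): a Mamba-2-style selective
  state-space model. The input is projected to a value and a gate path;
  the value path passes a pointwise depthwise convolution and SiLU,
  then generates per-timestep quantities: a scalar decay
  `a_t = exp(-softplus(a_base) * Delta_t)` with `Delta_t` a softplus of
  a learned linear map, and input/output maps `B_t, C_t` (state
  dimension 32). The recurrence `h_t = a_t h_{t-1} + B_t x_t'`,
  `y_t = C_t' h_t` is equivalent to multiplying the sequence by a
  lower-triangular semiseparable matrix `M` with
  `M_ji = C_j' (prod a) B_i`; the scalar-times-identity transition is
  exactly what makes this dual form valid. The package carries three
  interchangeable evaluation routes — the sequential scan, the dense
  materialized `M` (an intentionally quadratic oracle, refused beyond
  length 256), and a chunked evaluation that applies dense blocks
  within chunks of 10 timesteps and passes cross-chunk information
  through the low-rank state. Their three-way agreement on random
  instances is the module's core correctness surface. The compiled
  training path uses the dense route (at 50 frames the T × T matrix is
  tiny), which is numerically identical.

After each layer's temporal block the streams exchange information by
bidirectional cross-attention: queries from one stream, keys and values
from the other. Both directions are computed from the pre-exchange
features and added residually, so the exchange is symmetric and
order-independent. The alternation order (attention first) and the
residual-addition form of the exchange are fixed conventions; the
architecture leaves both open. Final features are mean-pooled over
time (parameter-free), concatenated across streams (78 values), and
classified by a linear layer + softmax into HC/PD probabilities.
Per-layer post-exchange features of both streams are returned for the
alignment loss.

## Training objective

The loss combines four terms:
`L = L_w + lambda1 * L_d + lambda2 * |W|_1 + lambda3 * |W|_2^2`.

* `L_w` is class-weighted cross-entropy, mean-reduced over the batch,
  with `w1 = 0.9` on the PD term and `w2 = 1.1` on the HC term —
  a mild compensation of the ~0.72:0.28 HC:PD imbalance (full
  proportional compensation overshoots). Probabilities are clamped to
  `[1e-7, 1 - 1e-7]`. Mean (not sum) reduction decouples the lambda
  scale from the batch size.
* `L_d` is the mean over layers of the squared maximum mean
  discrepancy (MMD) between the two streams' flattened per-layer
  features, with a Gaussian kernel whose bandwidth follows the median
  heuristic (`gamma = 1/median(pairwise distance)^2`, recomputed per
  batch and layer, treated as a constant in the gradient). The two
  views observe the same gait, so their feature distributions should
  agree; penalizing their discrepancy strengthens fusion
  (`lambda1 = 0.01`). The unbiased estimator can dip slightly below
  zero, so each layer's value is clamped at zero before averaging —
  the squared form is kept rather than its square root, whose gradient
  is unstable at zero. The estimator is computed on a random subsample
  of `min(batch, 64)` samples per step: the regularizer's expectation
  is unchanged while its cost, quadratic in the sample count on
  1950-dimensional flattened features, stays bounded.
* L1 (`lambda2 = 1e-4`) and squared-L2 (`lambda3 = 1e-3`) penalties
  apply to weight matrices only; biases, normalization gains, the
  per-channel convolution scale and the scalar decay base are exempt.

Optimization uses AdamW (beta1 0.9, beta2 0.99) with a piecewise
learning-rate profile: linear warm-up over the first fifth of training,
a constant plateau to the three-fifths mark, then linear decay (a
cosine decay variant sits behind a flag). The full-scale protocol is
1000 epochs at batch 3072 with the rate rising from 1e-8 to 1e-4 and
decaying to 1e-6. The reduced CPU protocol used throughout the tests
(`reduced_train_config()`) keeps the phase proportions and the
start/end-to-peak ratios but runs 60 epochs at batch 256 with peak
1e-3 — with two orders of magnitude fewer optimizer steps the peak
rate must rise for training to converge at all.

Evaluation is subject-grouped k-fold cross-validation: subjects, never
individual steps, are partitioned, so no person contributes to both
training and validation. Assignment is greedy (subjects in descending
sample count to the fold with the fewest subjects, ties by fewest
samples), followed by bounded one-for-one swaps that balance the PD
fraction across folds; everything is deterministic given the seed.
After every epoch the validation fold is scored and the parameters with
the highest validation F1 are checkpointed (ties keep the earlier
epoch). Metrics (accuracy, precision, recall, F1 — percent — and
rank-based AUC with ties counted one half) are computed per fold at the
step-sample level and aggregated by arithmetic mean; a subject-level
majority-vote accuracy is reported alongside but is not the primary
surface.

## Prior-information adjustment

Seven physiological priors (sex coded +1/-1, age, height, weight, BMI,
shoe size, single-step duration) can refine a trained model. Each field
is z-scored on the training subjects; a bias-free 7 × 2 linear map
turns the standardized priors into an adjustment that is added to the
frozen model's softmax output and passed through a final softmax. This
literal double-softmax form is kept because it is the stated design of
the method being implemented (a `logit`-space variant is available
behind a flag). Only the 7 × 2 matrix is fine-tuned — 500 epochs of
full-batch AdamW on the same loss family minus the MMD term, which has
no meaning without stream features; the class weighting is retained.
Because the inputs are z-scored and the map is bias-free, the learned
weights are directly comparable signed influences per prior, which is
the entire point of the design. BMI is recomputed as
weight/(height in m)^2 when absent.

## The synthetic cohort generator

No clinical recordings ship with the package, so every claim is
exercised on a synthetic dual-view generator with known ground truth.
Kinematics are phenomenological, not biomechanical: ankle elevations
follow antiphase sinusoids whose zeros are exact landing frames; knees,
hips, torso, head and arms are interpolated smoothly around a body
advancing at constant speed; the lateral view is the sagittal
projection and the frontal view the coronal one, with lateral sway and
a distance-dependent scale drift (the subject approaches the camera) so
that the two views' feature distributions genuinely differ and the
alignment loss has something to align. White coordinate noise stands in
for pose-estimator jitter, the confidence channel is Beta-distributed,
and stationary standing pads flank the walk. Oscillation amplitude
ramps in over half a gait cycle at each end so walking joins the pads
continuously; ground truth keeps a full-period margin from the ramps so
every recorded landing has full-amplitude neighbours.

Class structure at effect size 1 (scaled linearly by `effect_size`,
zero giving an exchangeable null cohort): healthy controls walk with
~50-frame steps (about 1.7 s), 40 px foot lift on a 350 px body, 90 px
step length and 0.8 px tremor; the PD class averages 4 frames longer
steps, 12 px lower lift, 30 px shorter steps and 2 px tremor —
slower, smaller-amplitude, noisier gait, the qualitative signature the
method targets, with amplitudes chosen so PD gait stays comfortably
above the segmentation prominence threshold (clinical PD steps are,
after all, segmentable). Priors are drawn with class-shifted means
(older, slightly lighter PD subjects; realized step duration is carried
into the priors table). Noise levels for the noisy-segmentation checks
are expressed as an RMS signal-to-noise ratio — RMS of the elevation
oscillation over the noise standard deviation — the standard ratio
definition; SNR 10 corresponds to ~1.4 px tremor at the default
amplitude.

What passing these tests shows: the pipeline's computations are
correct, leakage-free, and able to recover class structure that is
present in dual-view kinematics, while reporting chance on cohorts with
none. What it does not show: performance on real video, where pose
estimators fail in structured ways (occlusion, identity switches,
depth-dependent noise) that white jitter does not emulate, and where
gait pathology is far richer than three shifted parameters.

## Problem sizes and numerical choices

The validation suite runs on one CPU. Sizes were chosen as the smallest
that still make each claim meaningful: the separable-cohort run uses 60
subjects (about 230 step samples) under five-fold subject-grouped CV
with the 60-epoch reduced protocol; the null calibration uses 150
subjects with short recordings and 10 epochs, averaged over five
seeds, because a null AUC estimate is limited by the number of
*subjects*, not steps. The compiled training core works in single
precision with subnormals flushed to zero (gradients underflow float
range many layers deep; the hardware's subnormal path costs more than
a hundred cycles per operation and contributes nothing), uses a
polynomial `exp` approximation accurate to ~2e-7 relative, and routes
its allocations through a size-caching pool because the per-step
allocation pattern repeats exactly. The pure-R forward pass is kept in
double precision as the reference implementation; tests pin the
compiled path to it (probabilities to ~1e-4; deep-layer features
accumulate single-precision error through the normalization and decay
chains and are compared more loosely) and validate the compiled
gradients by finite differences. Checkpoints store parameters,
architecture configuration and preprocessing statistics in a
versioned single-file archive.

## Known limitations

Segmentation assumes the lateral view shows a roughly fronto-parallel
walk; the frontal view is never segmented on its own (perspective makes
single-step structure much harder to read there, and the fused model
always consumes lateral boundaries). Low-confidence keypoints pass
through unimputed. The generator's null cohort bounds false-discovery
behaviour only up to seed noise — with 150 subjects the AUC of a truly
null pipeline still varies by a few points. The double-softmax prior
adjustment compresses the adjustment's dynamic range; it is kept for
fidelity, with the logit variant available where calibration matters.
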