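---
title: "Classifying exercises from pose landmarks: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying exercises from pose landmarks: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

poseclass classifies repetitive exercises — squats, curls, push-ups and seven
other movements — from time series of 3-D body pose landmarks such as those
produced by the MediaPipe Pose estimator. This vignette explains the model and
its assumptions, the synthetic-data generator that makes the pipeline testable
without any external data, the tunable parameters, and the design decisions
taken where more than one reasonable choice existed.

## The classification model

### Input contract

The unit of input is a *pose sequence*: an ordered series of frames, each
holding the 22 non-facial body landmarks of the MediaPipe Pose convention
(indices 11–32: shoulders, elbows, wrists, the three finger landmarks, hips,
knees, ankles, heels and foot tips, on both sides). Facial landmarks carry no
information about exercise form and are dropped on load. Coordinates may be
image-normalized or metric; nothing in the pipeline assumes a particular
scale, because the angle features below are scale-invariant and the
coordinate features are consumed as-is by a network trained on data with the
same convention.

### Per-frame features: 66 coordinates + 12 joint angles

Each frame is reduced to 78 attributes:

* the raw landmark coordinates, 22 landmarks × (x, y, z) = **66 features**,
  in fixed registry order;
* **12 joint angles** in degrees. An angle is defined by three landmarks with
  the middle one as vertex; given the pairwise Euclidean distances
  $a = |p_1 p_2|$, $b = |p_2 p_3|$, $c = |p_3 p_1|$, the angle is the law of
  cosines

  $$\angle p_1 p_2 p_3 \;=\; \frac{180}{\pi}
    \arccos\!\left(\frac{a^2 + b^2 - c^2}{2ab}\right).$$

The default angle set covers the major limb joints on each side: elbow
(shoulder–elbow–wrist), shoulder (elbow–shoulder–hip), hip
(shoulder–hip–knee), knee (hip–knee–ankle), ankle (knee–ankle–foot tip) and
wrist (elbow–wrist–index). The set is a parameter (`default_angle_set()` is
just the default), because no canonical choice of "the" 12 joints exists;
any bilaterally symmetric set over the limb joints carries essentially the
same information, but classifiers trained with different sets are not
interchangeable.

Numerical care: the $\arccos$ argument is clamped to $[-1, 1]$ before
evaluation, because on near-collinear joints (a fully extended knee, say)
floating-point rounding pushes it marginally outside and would produce NaN.
A genuinely degenerate joint — two of its three landmarks coincide — has no
defined angle; the default policy is to raise an error, and a lenient mode
(`degenerate = "nan"`) exists for noisy real captures, in which NaN frames
are simply excluded from downstream votes and counted in a message.

Coordinate standardization (per-sequence centring/scaling of the 66
coordinate columns) is available but **off by default**: the classifier is
trained on raw coordinates, and angles are never standardized since they are
already translation- and scale-invariant. The flag exists for
experimentation with estimators that emit coordinates on wildly different
scales.

### The per-frame classifier

A one-dimensional convolutional network scores every frame independently.
The reference stack is

| layer | maps | size | kernel |
|-------|------|------|--------|
| input | 1 | 78 | – |
| conv  | 32 | 76 | 3 |
| pool  | 32 | 38 | 2 |
| conv  | 64 | 36 | 3 |
| pool  | 64 | 18 | 2 |
| conv  | 128 | 16 | 3 |
| pool  | 128 | 8 | 2 |
| conv  | 256 | 6 | 3 |
| pool  | 256 | 3 | 2 |
| flatten | – | 768 | – |
| dense | 512 | – | – |
| dense + softmax | 10 | – | – |

Convolutions are *valid* (no padding, stride 1), so a length-$L$ signal maps
to $L-k+1$; max pooling uses floor division, $L \mapsto \lfloor L/2 \rfloor$.
These two rules are forced by the size column above (78 → 76 → 38 → … → 3,
flatten $3 \times 256 = 768$) and `compute_layer_shapes()` reproduces it
exactly; a property test checks the arithmetic against an independent
brute-force recurrence on random stacks.

The network is implemented inside the package with base matrix algebra:
convolutions are lowered to matrix products via im2col, so all heavy
arithmetic runs in BLAS. Training minimises the categorical cross-entropy
with Adam (default learning rate $10^{-3}$, batch 64, 50 epochs), with ReLU
activations, He-uniform initialisation for the hidden layers and
Glorot-uniform for the softmax layer. None of these training choices is
canonical for this architecture — the task is not sensitive to them — and
all are exposed in `cnn_config()`. Dropout (between the hidden dense layer
and the output) defaults to 0 and exists as a regularisation knob.

Supervision is at the **frame level**: every frame inherits its sequence's
label. To prevent leakage of nearly identical neighbouring frames across
splits, train/validation/test splits are always made **by sequence**, never
by frame; this rule is hard-wired into the validation split, the k-fold
machinery and the tests.

Determinism: the seed controls initialisation, minibatch shuffling and
dropout masks through R's RNG. Bit-exact reproducibility of a training run
is promised in single-threaded BLAS execution; multi-threaded BLAS may
reorder floating-point reductions.

### Soft voting over frame windows

Per-frame probabilities are noisy — a single garbled frame (a pose-estimator
glitch) can be confidently wrong. The ensemble step pools the per-frame
probability vectors of $K$ consecutive frames by element-wise summation and
predicts the class with the largest summed score. Summing and averaging give
the same argmax, so the "sum" mode is the only one implemented. Ties are
broken toward the lowest class index; class indices are fixed alphabetically
over the ten names, since no other order is canonical.

The default window is **30 frames** (one second at 30 fps) with stride equal
to the window, i.e. one verdict per non-overlapping second. Thirty frames is
the point where windowed accuracy saturates while still allowing a fast
verdict; `accuracy_vs_frames()` recomputes that trade-off curve for any
model and test set. For latency-sensitive streaming a sliding mode
(`stride = 1`) emits one decision per frame after a 30-frame warm-up. A
sequence shorter than one window yields no window decision (with a warning);
the whole-sequence verdict `classify_sequence()` then falls back to one soft
vote over all its frames.

## The synthetic-motion generator

The generator exists so the full pipeline — features, training, ensembling,
evaluation — can be exercised end to end with data whose ground truth is
known by construction. It is a first-class, tested module, not a test
fixture.

Each class is caricatured by a *signature*: for each of the 12 default
joints, a sinusoid in degrees
$\theta_j(t) = \mathrm{clamp}\bigl(b_j + a_j \sin(2\pi f_j t + \phi_j),\,
5^\circ, 175^\circ\bigr)$, plus a whole-body trunk pitch (90° = upright, 0° =
lying) and, for the squat, a vertical pelvis bob. The defaults encode the
obvious kinematic caricatures — squat: large knee/hip oscillation; curl:
elbow oscillation only; bicycle crunch and bird dog: anti-phase left/right
limbs while horizontal; overhead press: shoulder and elbow extension above
the head — at frequencies between 0.4 and 1 Hz, i.e. realistic repetition
tempos. Every pair of classes differs by at least 15° in some joint's
baseline or amplitude; `validate_signatures()` enforces this, so a
misconfigured registry that makes two classes kinematically
indistinguishable fails fast rather than producing a mysteriously bad model.

Forward kinematics turns the angle trajectories into landmark positions over
a fixed-segment skeleton (segment lengths in metres, e.g. torso 0.52, thigh
and shank 0.42). Two geometric simplifications are deliberate:

* **Planar-dominant motion.** Each body side's limb chain lies in a plane
  parallel to the sagittal plane, with fixed small z offsets separating the
  sides and the finger landmarks. Interior joint angles measured back from
  the generated landmarks therefore reproduce the input trajectories
  *exactly* (the closed-loop test demands agreement within $10^{-3}$
  degrees); generator and feature extractor act as mutual oracles.
* **Equal shoulder and hip width.** Anatomically shoulders are wider, but
  equal widths are what keep each side's chain exactly planar, which the
  closed-loop property depends on.

Noise is applied last: i.i.d. Gaussian jitter on every coordinate (default
sd 0.0052, i.e. 1% of the torso length — a typical relative jitter for
frame-to-frame pose-estimator output), and **outlier frames**: with
probability 0.05 a frame's landmarks receive 10× the base jitter, emulating
the occasional catastrophic pose-estimation failure that the frame ensemble
is designed to absorb.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: perspective projection and camera motion, occlusion
(systematically missing or displaced landmarks rather than i.i.d. jitter),
anthropometric variation between subjects, tempo drift within a set,
out-of-plane rotation of the whole body, and the correlated, heteroscedastic
error structure of real pose estimators. Results on simulated data are a
verification of the pipeline's mechanics and of the ensemble's
outlier-robustness rationale, not an estimate of real-world accuracy.

## Evaluation machinery

`compute_metrics()` reports accuracy (trace over total of the confusion
matrix), per-class precision, recall and F1, and both macro (unweighted over
classes) and support-weighted aggregates; macro is the headline since the
datasets here are balanced. A class that never receives a prediction has
undefined precision; it is reported as 0 with an explicit
`precision_defined = FALSE` flag, never silently dropped. The unit of
evaluation is the **window decision** throughout (not the frame, not the
video), matching how the classifier is used; per-video verdicts are
available via `classify_sequence()`.

`stratified_kfold_evaluate()` (default $k = 5$) stratifies by class at the
sequence level, trains one model per fold and sums the fold confusion
matrices; pooled accuracy is provably trace/total of the summed matrix, and
a test asserts this identity on a real run.

## Problem sizes used by the packaged checks

The package's own end-to-end check — also what `scripts/acceptance.R`
reruns — simulates 10 classes × 20 sequences × 120 frames at 30 fps under
the default noise model, holds out 5 sequences per class (split by
sequence), trains the reference network for 10 epochs at batch 64, and
scores the held-out sequences at $K = 1$ and $K = 30$. Ten epochs were fixed
once as comfortably past convergence on this task (the training log shows
the loss plateauing well before that); the unit-test fixture uses a smaller
dataset (4 sequences × 60 frames per class, 6 epochs) that is shared across
test files. On this synthetic task the expected behaviour is near-ceiling
window accuracy (≥ 0.95) and a window-over-frame gain, since the classes
are separable by construction; neither number transfers to real captures
(see the simulator's non-goals above).

## Known limitations

* The identity of the 12 angles consumed by a trained network is a
  convention; mixing angle sets between training and inference is an error
  the feature-width check only partially catches (any 12-angle set has
  width 78).
* Training is CPU-bound R/BLAS; it is sized for desk-scale experiments
  (tens of thousands of frames), not for large video corpora.
* The whole-sequence verdict assumes one exercise per sequence; sequences
  containing transitions between exercises produce one verdict per window,
  and segmentation is out of scope.
* Real-data ingestion expects landmark files; running a pose estimator on
  video is an adapter concern outside the package.
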