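---
title: "Multimodal fall detection: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fall detection: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallfusion)
```

## The problem

A fall detector for a single person in a small indoor space watches two
signals from one non-intrusive device: the video stream, reduced to a
per-frame track of 17 anatomical keypoints, and the microphone. Each 3-second
clip must be labelled *fall* or *not-fall*. The two modalities fail in
different ways — video misses falls that happen off-screen, behind furniture
or in the dark, audio confuses soft falls with stomps — so the package
classifies each modality separately and merges the two clip-level
probabilities at the decision level.

This vignette documents the models, every tunable that matters, and the
choices made where the design was genuinely open.

## Video branch

### Skeleton representation

Each frame is a 57-element pose prediction vector: box center, width, height,
box and class confidence, then 17 keypoint triples `(x, y, score)` in COCO
order (`coco_keypoints()`). Coordinates are image pixels with the origin at
the top-left and y growing downward; all kinematics below use that
convention. `read_sequence()` accepts keypoint JSON or CSV, orders frames by
index, and removes *blank* frames — frames whose 17 scores all fall below a
threshold (default 0.05, configurable), the signature of a person entirely
out of view.

`normalize_sequence()` centers each frame at the hip midpoint and divides the
whole clip by its median torso length (hip midpoint to shoulder midpoint),
making the features invariant to where the person stands and how large they
appear. Both properties are asserted to 1e-9 in the test suite. Occluded
keypoints (score 0) stay at the origin after centering rather than being
interpolated — the simplest convention, and one the network can learn to
ignore because the score channel is available. The motion stream is the
first difference of consecutive frames with a zero leading frame, so both
streams share the shape `T x 17 x C`.

### Skeleton graph and partitions

The joint graph connects naturally adjacent joints (nose–eyes–ears chain,
arms, legs, pelvis, shoulder–hip trunk links; 19 edges, connected). The
neighborhood of a joint is itself plus its 1-hop neighbors. Three partition
strategies split that neighborhood into subsets that share convolution
weights: `uni-label` (one subset), `distance` (self vs. neighbors), and
`spatial` (root, centripetal, centrifugal by hop distance to a center joint —
the nose by default, the only sensible anatomical center among the COCO 17).
The spatial strategy is the default, as is standard for skeleton action
recognition.

Every partition matrix is normalized by the *receiving joint's neighborhood
size*, so the stacked operator is row-stochastic: applied to a constant node
signal it returns that constant, and no joint is privileged by its degree.
The normalization term in the spatial convolution is exactly this
neighborhood cardinality. `spatial_graph_conv()` is verified against a
brute-force double sum over neighborhoods on random small graphs to 1e-10.

### Two-stream ST-GCN

Each stream (joint positions; frame differences) passes through nine
spatio-temporal layers. A layer is: graph convolution over joints within
each frame, batch normalization, ReLU, then a temporal convolution (kernel
Γ = 9 frames, odd so the window is symmetric) across corresponding joints,
batch normalization, dropout, a residual connection, and a final ReLU.
Temporal strides of layers 4 and 7 are 2, so 75-frame clips shrink to
38 and then 19 frames — the closed form `ceiling(ceiling(75/2)/2)` is
asserted in the tests. Dropout is 0.5. Global average pooling over time and
joints yields one feature vector per stream; the two are concatenated into a
fully connected sigmoid head that outputs the fall probability. Training
minimizes binary cross-entropy (predictions clipped at 1e-7) with Adam at
learning rate 1e-3.

Open points settled as package conventions:

* **Channel plan.** The canonical progression 64, 64, 64, 128, 128, 128,
  256, 256, 256 is the `video_config()` default. The synthetic benchmark
  uses `video_benchmark_config()` — the same nine-layer/stride structure at
  widths 4/8/16 with 8 epochs, which a single CPU trains in about two
  minutes on 208 clips.
* **Streams do not share weights**; they are merged only at the head.
* **Residual connections** are enabled except in the first layer (where the
  channel count jumps from the raw input).
* **Dropout placement.** Dropout sits after the second batch normalization
  of each layer, never before one: normalization statistics estimated on
  dropout-corrupted activations are wrong at inference time.
* **Batch-statistics refresh.** After the last epoch the batch-norm running
  means and variances are re-estimated in one clean full-batch pass. Short
  training runs otherwise leave the momentum-averaged statistics lagging the
  final weights, which silently destroys inference-mode accuracy.
* **Determinism.** One seed controls initialization, shuffling and dropout;
  two runs with the same seed produce identical histories.

### Frame-level inference and the consecutive-frame rule

A sequence classifier yields per-frame scores by sliding a window (default
45 frames, stride 1; stride 5 in the pipeline for speed) and giving each
frame the probability of the window centered nearest to it, so every frame
is covered. `aggregate_frames()` then binarizes at 0.5 and declares a fall
iff some run of at least 15 consecutive frames is fall-positive. The fall
confidence is the maximum, over maximal qualifying runs, of the mean frame
probability within the run. Two readings were possible ("any window" vs.
"maximal runs"); maximal runs were chosen because a run's mean is the
natural confidence of the *event*, and the choice is verified against an
exhaustive window scan in the tests. A clip with no qualifying run still
needs a fall probability for fusion; the package uses the maximum
15-frame sliding-window mean, which degrades smoothly near the decision
boundary instead of jumping to zero. Ties at exactly 0.5 are classified
not-fall everywhere — conservative for specificity.

## Audio branch

### Preprocessing and augmentation

`energy_gate_trim()` replaces manual noise-segment editing: leading and
trailing regions whose short-time RMS sits more than 40 dB below the clip's
peak are cut, with 50 ms of context kept. An all-quiet clip is returned
unchanged with a warning flag rather than emptied.

Five label-preserving augmentations expand a corpus sixfold (originals plus
one clip per method): white noise at 20 dB SNR, time-axis lengthening (×1.2)
and shortening (×0.8) by resampling, and ±6 dB gain. Gains are applied
without hard clipping so opposite gains invert exactly; 260 clips become
1560.

### Log-mel spectrograms

Defaults: 16 kHz audio, FFT 1024, hop 512, 64 mel bands (triangular HTK-mel
filterbank from 0 Hz to Nyquist), log10 power with floor 1e-10. Centering is
off, so a length-L clip yields `1 + floor((L - n_fft)/hop)` frames. All
parameters are configurable; none were stated by any reference pipeline, so
they follow common audio-classification practice. Two properties pin the
implementation down in tests: silence sits exactly at the log floor, and a
gain g shifts every unfloored value by `2*log10(g)`.

The spectrogram is resized bilinearly to the classifier's square input and
rescaled by a *fixed* affine map (log floor to -1, unit power to +1).
Per-image standardization was rejected deliberately: absolute level carries
class information — an impact is loud — and a per-image standard score makes
a soft footstep look like a scaled-down impact.

### MobileNetV2

The classifier is the standard inverted-residual architecture: a 3x3 stem at
stride 2, seven bottleneck stages with expansion factors and strides
(1,16,1,1), (6,24,2,2), (6,32,3,2), (6,64,4,2), (6,96,3,1), (6,160,3,2),
(6,320,1,1), a 1x1 convolution to 1280 features, global average pooling,
dropout and a 2-way softmax. Depthwise 3x3 convolutions carry the spatial
work; projections are linear (no activation). With a 224 input the spatial
trace is 112, 112, 56, 28, 14, 14, 7, 7, asserted against the schedule. A
width multiplier scales all channel counts, rounded to multiples of 8, and
the parameter count is checked against a closed-form sum over the schedule.

The desk-scale benchmark (`mobilenet_benchmark_config()`) trains width 0.25
at 32x32 input from random initialization, which needs a hotter learning
rate (3e-3) and about 45 epochs; the full-width default keeps the 1e-3 rate
appropriate for fine-tuning. Adam carries an L2 weight-decay term (1e-4).
The same batch-statistics refresh as the video branch is applied after
training.

`kfold_evaluate()` provides stratified 5-fold cross-validation (each sample
tested exactly once, fold sizes within one per class) and reports the five
metrics per fold with their averages.

## Decision fusion

Both branches emit a clip-level fall probability: the video branch via the
consecutive-frame rule, the audio branch from its softmax. Linear fusion
computes `c = alpha*a + (1-alpha)*b` with the video weight `alpha` intended
in [0.6, 0.9] (audio is the supplement; values outside warn but do not
error). The pipeline sweeps alpha over {0.6, 0.7, 0.8, 0.9}.

Dempster–Shafer fusion works on the frame of discernment {fall, not-fall}.
A classifier probability p becomes a mass function
`m({fall}) = (1-d)p, m({not-fall}) = (1-d)(1-p), m(Θ) = d` with discount d
(default 0); the discount models limited trust in a source by reserving mass
for total ignorance. Dempster's rule combines two masses by routing the nine
product terms through set intersection, with the conflict
`K = m1({fall})m2({not-fall}) + m1({not-fall})m2({fall})` renormalizing by
`1/(1-K)`. One printed form of the conflict definition in circulation is
self-contradictory (it sums the *non*-empty intersections and equates the
result to its own complement); the package implements the standard
empty-intersection conflict, which is the only definition consistent with
the `1/(1-K)` renormalization. Total conflict (K = 1) raises an explicit
error. With discount 0 the rule reduces to the Bayesian product posterior
`ab / (ab + (1-a)(1-b))` — an algebraic identity the tests exploit as an
independent cross-check. Decisions default to the pignistic probability
`m({fall}) + m(Θ)/2 > 0.5`; a pure-belief rule is available.

## Evaluation

With fall as the positive class: sensitivity TP/(TP+FN), specificity
TN/(TN+FP), accuracy, precision TP/(TP+FP), and F1 = 2TP/(2TP+FP+FN), all
reported as percentages. Display rounding is half-up to two decimals (base
R's round-half-even does not reproduce conventionally printed tables);
internal values keep full precision. Zero denominators yield an explicit
"undefined", never a silent zero.

## The synthetic corpus

`gen_dataset()` emulates the study conditions end to end: 130 fall and 130
non-fall paired clips, 3 s at 25 fps (75 frames) in a 320x240 frame, audio
at 16 kHz. Falls descend 60 px at the hip within 0.6 s while the body axis
rotates toward horizontal, with onset uniform in [0.8, 1.6] s; daily
activities are periodic gait (with soft footstep transients in the audio),
a slow 30 px sit-down over 1.2 s, and a squat-and-rise. Keypoints carry
high scores with 2% dropout; coordinates get 1.5 px jitter. Fall audio adds
a damped broadband burst (0.2 s, peak 0.5 over 0.01 RMS ambient noise)
time-locked to the end of the skeletal descent; the coupling can be severed
to study fusion under modality conflict. These values were chosen once as a
plausible emulation of indoor fall recordings — the descent rate is several
times any daily activity's, and the impact crest factor far exceeds
footsteps' — and the class-separability the pipeline relies on is itself
asserted in the tests (a linear model on max 5-frame hip descent and audio
crest factor separates the classes perfectly at defaults).

What the generator does *not* emulate: camera perspective and lens effects,
multiple people, furniture occlusion patterns, reverberation and
room-transfer acoustics, vocal interference, and pose-estimator failure
modes beyond isotropic jitter and random dropout. Passing the training
benchmarks therefore shows that the networks, losses and fusion rules are
implemented correctly and can recover strong class structure — not that the
same configurations would reach the same numbers on real recordings.

`gen_modality_scores()` generates the complementary-error operating regime
directly: video wrong on ~18% of clips, audio on ~5%, independently, with
confident correct predictions (mean margin ~0.92) and hesitant errors (mean
~0.60). In this regime both fusion rules beat the better single modality —
the linear rule because a hesitant video error is outvoted by a confident
audio opinion even at alpha 0.7, Dempster's rule more strongly because the
product form amplifies whichever source is more certain. That benefit is a
seeded, averaged assertion in the acceptance suite.

## Problem sizes and numerical choices

The shipped benchmark trains on 208 of 260 synthetic clips (stratified 8:2
split at clip level) — roughly two minutes for the video branch and five for
the audio branch on one CPU — sizes chosen so the whole suite runs
comfortably at a desk. Numerical constants: BCE clipping 1e-7, log-power
floor 1e-10, batch-norm epsilon 1e-5, mass-function normalization tolerance
1e-9, oracle agreement tolerances 1e-10 (graph convolution) and 1e-12
(Dempster combination, metric identities). All randomness flows from
explicit seeds; derived per-stage seeds are small integer offsets of the
root seed.

## Limitations

* The networks are implemented in plain R matrix code. That keeps the
  package dependency-free and auditable down to each gradient, and is fast
  enough for the shipped problem sizes, but it is not a platform for
  full-scale training: the canonical 64-channel plan at hundreds of epochs
  belongs on a GPU framework.
* The video branch assumes exactly one tracked person per clip; multi-person
  scenes and identity switches are out of scope.
* Frame-level scores come from sliding windows, so very short events (under
  half a window) are smoothed; the 15-frame rule then decides at clip level.
* The D–S mass construction from classifier outputs is a convention (the
  discount parameter is exposed); alternative conflict-handling rules are
  not implemented.
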