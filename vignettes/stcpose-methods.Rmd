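---
title: "Semi-supervised temporal pose estimation: models, losses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised temporal pose estimation: models, losses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Markerless pose estimation for swimming fish — recovering K = 21 named
anatomical landmarks per video frame — faces two structural obstacles that
frame-by-frame supervised pipelines (the DeepLabCut/SLEAP family) do not
address. First, dense manual annotation of aquatic video is expensive, so
labeled sets are small while unlabeled video is abundant. Second, single-frame
prediction is brittle under occlusion and motion ambiguity: a fin crossing the
body produces either a low-confidence outlier (catchable by thresholding the
network's confidence) or, worse, a high-confidence misprediction that only
reveals itself as a biologically implausible jump in the keypoint trajectory.

`stcpose` implements a semi-supervised, temporally aware estimator that
attacks both: a five-frame bidirectional convolutional-recurrent fusion head
adds temporal context to the heatmap decoder, and two unsupervised hinge
losses extract training signal from unlabeled clips.

## Model

The estimator is a standard heatmap pipeline. A convolutional backbone
downsamples the input frame to a feature grid; an upsampling head
(sub-pixel/pixel-shuffle rearrangement followed by transposed-convolution
stages) produces one raw score map per keypoint; a spatial softmax turns each
map into a probability distribution over pixels, and the soft-argmax — the
probability-weighted expectation of pixel coordinates — yields a
differentiable sub-pixel location. The peak probability of each normalized
map serves as the keypoint's confidence. Coordinates are `(x, y)` = (column,
row), 0-based, origin at the top-left pixel centre; heatmap-grid coordinates
are mapped to image pixels by the ratio `image_size / heatmap_size`.

Two backbones are built in. `"tiny"` (three 3×3 stride-2 convolution blocks,
tanh, ~50k parameters, ×8 downsampling) is first-class: it trains in minutes
on one CPU and is what every experiment in the test suite uses. `"resnet50"`
constructs the full bottleneck stack (×32 downsampling; a 256×256 input gives
the 8×8×2048 feature grid) for full-scale work; it is built without batch
normalization and without pretrained weights (none are bundled), and only its
shape contracts are exercised by the tests.

### Temporal fusion head

For video, five consecutive per-keypoint heatmaps feed a bidirectional
convolutional recurrence: `h' = tanh(ConvX(x) + ConvH(h) + b)` with 3×3
kernels, zero initial state, and independent parameter sets for the forward
(frames 1→5) and backward (5→1) branches. The two hidden states at the centre
(3rd) frame are averaged pixel-wise and projected to a single channel by a
shared 1×1 convolution; decoding then proceeds exactly as in the single-frame
path. Parameters are shared across keypoints (the keypoint axis is treated as
a batch), so the head's cost is independent of K's identity and predictions
for one keypoint cannot depend on permuting the others. Since steps after the
centre frame cannot influence the centre state, each branch is unrolled only
three steps — an exact optimization, not an approximation.

The default hidden width is 8 channels (configurable via `rnn_hidden`). This
is a deliberate desk-scale capacity choice: the recurrence dominates training
cost, which scales linearly in the width times the heatmap area, and widths
beyond this bought no measurable accuracy on the synthetic task while
multiplying runtime.

## Losses

Training minimizes `L_total = L_RMSE + α·L_T + β·L_P` with α = β = 1 by
default. Setting both to zero recovers purely supervised training, and the
loss modules are inert at inference: predictions from a checkpoint are
bit-identical whether or not the loss machinery is attached.

**Supervised RMSE** (`L_RMSE`): root mean squared Euclidean distance, in
pixels, between predicted and annotated keypoints over the visible keypoints
of each labeled frame. Computed on soft-argmax coordinates, so the whole
image→coordinate path is differentiable.

**Temporal continuity** (`L_T`): real motion is continuous, so a keypoint
should not jump between consecutive frames. For each keypoint k and frame
pair, the hinge `max(0, ‖y_k^t − y_k^{t−1}‖₂ − ε_k)` penalizes only
displacements beyond a per-keypoint threshold; small within-threshold motion
(and measurement noise) is free. Thresholds differ per keypoint because body
parts move by different amounts — a tail tip travels much farther per frame
than a snout. `calibrate_eps_temporal()` sets `ε_k` to the q-quantile
(default 0.95) of observed inter-frame displacements on reference
trajectories; at q = 1 genuine motion in the reference never incurs loss.

**Pose plausibility** (`L_P`): although 2K coordinates can mathematically
move anywhere, real body configurations occupy a low-dimensional subspace.
PCA on the flattened labeled training poses (interleaved layout
`(x₁, y₁, …, x_K, y_K)`; frames with any occluded keypoint dropped) yields a
mean pose μ and orthonormal components P retaining 99% of variance. A
predicted pose ŷ is reconstructed as `ỹ = (ŷ − μ) P Pᵀ + μ`; per keypoint,
the hinge `max(0, ‖ŷ_k − ỹ_k‖₂ − ε)` penalizes reconstruction error beyond
the calibrated threshold ε, the maximum per-keypoint reconstruction error
observed on the training poses themselves. Poses inside the subspace are
exact fixed points and incur no loss. PCA requires at least 2K valid training
poses; below that the covariance is rank-deficient and the trainer disables
the pose term (with a message) rather than fit an unidentifiable subspace.
The subspace is fitted once on labeled poses and frozen — predictions on
unlabeled data never update it, which prevents the prior from drifting toward
the network's own errors.

Both hinges are aggregated by the mean over their (pair, keypoint) or
keypoint terms, keeping the loss scale independent of K and of the window
length. In the gradient path, Euclidean norms carry a 1e−12 floor inside the
square root so gradients stay finite at zero displacement; reported values
use the exact norm. The temporal hinge is invariant under a global
translation of all poses; the pose hinge deliberately is not (a translated
pose leaves the subspace).

## Training loop

Each optimizer step combines `batch_size` labeled frames with one sampled
unlabeled clip window (default 6 frames — the shortest window that yields a
consecutive pair of five-frame centre predictions). Labeled frames are static
images; when the temporal head is active they are presented as a replicated
five-frame window, so the head is supervised on the degenerate static case
while the unsupervised losses teach it motion. Interior frames of the
unlabeled window are predicted by sliding the five-frame head; the temporal
hinge acts on consecutive pairs and the pose hinge on each predicted pose.
Optimization is Adam with the step schedule lr₀ = 0.001 halved at epochs
150/200/250, batch size 6, and 300 epochs by default; the backbone is frozen
(gradients zeroed, weights bit-identical) for the first 20 epochs, a guard
that matters when starting from pretrained features. Validation RMSE on a
held-out labeled fraction (default 20%) is computed every epoch and the
best-validation checkpoint is kept alongside the final one. With identical
seed and configuration two runs produce identical histories; when α = β = 0
the run matches a supervised-only run step for step because no unlabeled
sampling consumes the RNG stream.

## The synthetic fish generator

Annotated carp video of the kind this method targets is rarely shareable,
so `fishsim` provides the study conditions synthetically: a single carp-like body of 21
keypoints (15 midline points, two pectoral pairs, a dorsal-fin point, a tail
tip) swimming with carangiform kinematics. The midline at arc position
s ∈ [0, 1] is displaced laterally by `A(s)·sin(2π(s/λ − σ·f·t))` with a
tailward-growing envelope `A(s) = a_head + (a_tail − a_head)s²`; σ = +1 sends
the wave tailward (straight swimming), σ = −1 headward (backward swimming),
and a nonzero heading rate produces turning. Frames render the body as
Gaussian blobs of tapering radius with additive background noise, in a
fish-centred crop (as pose pipelines crop around a detection); rectangular
occluders hit 10% of frames, zero their coverage, and flip the visibility of
covered keypoints. Ground truth is frame-synchronous by construction, and the
generator is byte-deterministic given a seed.

Defaults mirror the emulated composition: 400 labeled static frames sampled
across the three gaits plus 20 unlabeled ten-second clips; the frame side
(64 px) and clip frame rate (10 fps) are desk-scale choices. What the
simulator does **not** emulate: water optics, lighting variation, multiple
fish, photorealistic texture, or hydrodynamically accurate kinematics. A
passing test suite therefore shows the method's machinery is correct and that
its semi-supervised signal helps under controlled degradation (occlusion,
noise); it does not certify accuracy on real underwater video.

A useful structural property holds by construction: straight-gait poses live
on an (almost exactly) low-dimensional manifold — the traveling wave at fixed
heading decomposes into two linear modes — so the fitted subspace reaches 99%
variance with rank far below 2K, which is what makes the plausibility loss
meaningful on this data.

## The scaled ablation

`ablation_run()` replicates, at desk scale, the central comparison: the
supervised single-frame baseline versus the full semi-supervised temporal
model, trained under matched seeds on the same data. Problem sizes, fixed up
front as the package's own choice: 40 labeled frames + 4 three-second clips
at 8 fps and 64 px for training; two fresh five-second clips (seed offset
500000) for held-out evaluation; tiny backbone; 50 epochs; fusion width 4;
no backbone freezing, because the backbone is randomly initialized and there
are no pretrained features to protect. Both models are scored on the same
interior frames (those with full five-frame coverage), and jump outliers are
counted against thresholds calibrated at q = 1 on the evaluation ground
truth. At this scale 40 labeled frames cannot satisfy the 2K = 42 PCA
precondition, so the pose term is inactive and "semi-supervised" means the
temporal head plus the temporal continuity loss — the trainer reports this
explicitly.

On this benchmark the semi-supervised temporal model roughly halves the
held-out RMSE of the baseline; the numbers for any seed are reproduced by
`scripts/acceptance.R`, which writes them as JSON.

## Numerical and design notes

- **Decoding.** Spatial softmax subtracts the per-map maximum before
  exponentiating (shift invariance; no overflow). The softmax temperature is
  exposed (default 1); decoding after temporal fusion uses soft-argmax
  everywhere, including where a hard argmax would be tempting, because the
  losses require differentiability end-to-end.
- **Gaussian targets.** `render_gaussian()` produces unit-sum probability
  maps (not unit-peak), so the soft-argmax of a target recovers its centre
  and confidences are well-scaled; border-truncated kernels are renormalized.
- **PCA determinism.** The subspace uses a full symmetric eigendecomposition
  (no randomized solver); each component's sign is fixed by forcing its
  largest-magnitude entry positive, so the retained rank and components are
  reproducible across runs. Zero-variance data defines rank 0 with
  reconstruction collapsing to the mean. The retained rank is additionally
  capped at `min(N − 1, 2K)`.
- **ε conventions.** The pose threshold is a global scalar (the maximum over
  frames and keypoints), with a per-keypoint variant exposed as an option;
  the temporal thresholds are per-keypoint by construction.
- **Window semantics.** A temporal model predicts frames `3 … T−2` of a
  T-frame clip (one pose per full five-frame window); edge frames get no
  temporal prediction unless the caller opts into base-head fallback.
- **Degenerate configurations.** The identity fusion head (1×1 unit input
  convolution, zero hidden convolution, linear activation, unit projection)
  makes temporal decoding collapse exactly to single-frame decoding — used
  as an equivalence oracle in the tests. Zero loss weights collapse training
  to the supervised baseline.
- **Engine.** The conv-net layers (convolution, transposed convolution,
  pixel shuffle, max pooling) are implemented in C++ (RcppArmadillo) as
  im2col/col2im plus GEMM with hand-written adjoints; every adjoint is
  finite-difference checked in the test suite. Input normalization uses the
  mean/sd of the labeled training images.

One caveat the ablation exposes about the jump-outlier count as a smoothness
metric: it only discriminates between models that actually track. A
supervised baseline that underfits into a near-static predictor produces few
displacement flags trivially — it barely moves — while failing the task by
RMSE. Jump counts should therefore be read jointly with RMSE, never alone;
on seeds where the baseline collapses this way, the semi-supervised model
can show more flags despite halving the error.

## Known limitations

Single fish only (no detection or identity management); 2D only; the
resnet50 configuration is shape-tested but not trained anywhere in the suite;
the temporal window is fixed at five frames; checkpoint archives are R RDS
files, not portable across frameworks. The synthetic benchmark is a
controlled stand-in — conclusions about real video require real annotations.
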