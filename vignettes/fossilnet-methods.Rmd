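---
title: "Few-shot microfossil recognition: models, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot microfossil recognition: models, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Acid digestion of early-Cambrian phosphorites yields residues containing
thousands of sub-centimetre fossils: tubes, spheres, spines, shells and a
large amount of irregular debris. Taxa of high scientific value are rare —
often only a handful of specimens exist — so a classifier that needs
thousands of labelled images per taxon is useless for exactly the fossils
one most wants to find. `fossilnet` implements the transfer-learning answer
to this: pretrain a deep residual network on a large, readily available
source domain, then retrain only part of it on the few target images
available per taxon.

## The backbone

The classifier is the classic 34-layer residual network: a 7×7/stride-2
stem convolution with 3×3/stride-2 max pooling, four residual stages of
(3, 4, 6, 3) two-convolution units at (64, 128, 256, 512) channels, and a
global-average-pool + fully-connected head. The stem, the 32 unit
convolutions and the head give the 34 weighted layers on the inference
path. Each unit adds its input to the branch output before the final
rectification: `y = relu(x + F(x))` for the identity ("solid-line")
shortcut. The first unit of each of the last three stages halves the grid
and doubles the channels, so its shortcut is a 1×1/stride-2 projection
convolution plus batch norm (the "dashed-line" mechanism); there are
exactly three such units. Batch normalisation follows every convolution
(standard for this architecture, and not counted toward the depth);
activation is the rectifier, applied after each batch norm and after each
shortcut addition.

Because no tensor/autodiff engine is available to R in this environment,
the network — forward pass, backward pass, and the Adam optimiser — is
implemented in the package itself: convolutions run as im2col + BLAS
matrix products in C++ (`RcppArmadillo`), with hand-derived gradients for
convolution, batch normalisation and max pooling. All kernels are verified
against central-difference numerical gradients in the test suite's
development history and against architectural invariants (zero-branch
identity, shape contracts) in the shipped tests.

Numerical choices worth knowing:

* Initialisation is He (fan-out) for convolutions, unit scale / zero shift
  for batch norms, and a small uniform draw for the head; all draws are
  seeded and the initialisation is reproducible bit-for-bit.
* Batch-norm statistics use the population variance over `(H, W, N)`,
  momentum 0.1, epsilon 1e-5. Inference always uses running statistics.
* Softmax ties at prediction time break toward the lowest class index.
* The checkpoint container is a single-file named-tensor archive
  (little-endian 64-bit floats) that round-trips every tensor bit-exactly;
  loading validates the full key set and refuses silently mismatched heads.

The canonical input side is 224 (the convention inherited from pretrained
natural-image models, and the package default). The head is size-agnostic
through global average pooling, so `build_resnet34(input_side = ...)`
accepts smaller sides; the desk-scale experiments below run at side 32.

## Transfer strategies

A freeze plan assigns each block of
`conv1, conv2_x, conv3_x, conv4_x, conv5_x, fc` to *frozen* (parameters
retained from the pretrained model) or *trainable* (retrained on target
data):

* **TF** — only the fully connected head is trained.
* **TS(k)** — blocks from `k` onward are retrained; earlier blocks keep
  their pretrained parameters as generic feature extractors. All four
  variants (`k` from `conv2_x` to `conv5_x`) are supported.
* **TA** — everything is retrained from the pretrained starting point.

Every supported plan freezes a contiguous prefix. Frozen blocks run in
inference mode, so their batch-norm running statistics are retained
bit-exactly along with their weights — "retained" is read strictly. This
prefix structure is also what makes the experiment harness cheap: the
forward pass through the frozen prefix is computed once per strategy and
its features are reused across every group, size and epoch. That reuse is
an exact algebraic factorisation of the naive computation (verified
against the direct path in the tests), not an approximation.

Training minimises softmax cross-entropy with Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8). The learning rate defaults to 1e-4 and the batch size to 16,
the settings of the original study; the epoch count is not stated there,
so the package default is 30 with explicit overrides everywhere. A zero
learning rate is an exact no-op (no parameter, moment or running-statistic
changes), which gives tests a clean null. The last incomplete batch is
kept — few-shot training sets are routinely smaller than one batch.

## Preprocessing and augmentation

Training images pass through: chroma-key background removal (a pixel is
background when its hue lies within a window of the uniform imaging blue
and its saturation and value clear minimum floors; matched pixels become
black), affine augmentation (translation ≤ 10% of the side, rotation ≤ 30°,
shear ≤ 10°, scale in [0.8, 1.25] — bounds chosen here, as the source
protocol names the transform families but not magnitudes), Gaussian pixel
noise (σ = 8 on the 0–255 scale), centre-crop + bilinear resize to the
network side, and per-image, per-channel standardisation
`(X − X_mean)/X_std` with the population standard deviation. A channel
with standard deviation below 1e-8 is emitted as zeros and flagged rather
than divided through. Augmentation applies only to training samples, after
the raw train/test split: the held-out test set is never augmented, which
is the leakage-free reading of an ambiguous protocol; each original yields
five augmented copies by default (a multiplicity the source never states).

The affine operations are implemented as inverse-mapped resampling with a
bilinear default and an exact nearest-neighbour mode; zero-magnitude
transforms are bit-exact identities, and right-angle nearest rotations are
pure pixel permutations — both properties the oracle tests rely on.

## Evaluation protocol

Evaluation follows the repeated-subsampling design: a fixed, balanced test
set is drawn once per experiment; for every per-class training size a
number of independent balanced groups are drawn from the remaining pool;
each (strategy, size, group) trains a fresh model — pretrained body, newly
seeded head — and is scored on the single test set; group scores are
averaged. Metrics are the confusion-matrix classics: per-class precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1, unweighted
macro averages, and the misjudgment rate `1 − accuracy`. Any 0/0 is
defined as 0 and flagged. "Average F1" is the macro average: with a
balanced test set the macro and weighted versions coincide. Group seeds
derive deterministically from the experiment seed, and the entire grid is
reproducible from one integer.

The machine-learning comparator is histogram-of-oriented-gradients
features (cell 8 px, 2×2-cell blocks at stride 1, nine unsigned
orientation bins, magnitude-weighted hard assignment, L2 block
normalisation — the defining parameters are not printed in the source, so
these common defaults are used) with a radial-basis SVM (C = 10,
γ = 1/dim). It plugs into the identical splits and metrics.

## The synthetic data, and what it does and does not show

The package generates its own imagery so every stage is testable without
downloads. Nine shape families mirror the visual character of the real
taxa — cone-shaped tube, sphere, stepped cone tower, curved tapering
spine, ridged shell cap, four-slotted tube, sinusoidal worm, transversely
segmented tube, and an irregular-dross class of random blob unions —
rendered as speckled greyscale fossils (white, grey or black bands,
matching phosphatized specimens) on the uniform blue imaging background
(RGB 40, 90, 200, ±3 sensor noise). Each image jitters size (±15% around
75% of the frame), position, orientation and family shape parameters, and
is clipped to a fragment by a random chord with probability 0.25 (0.4 for
dross, whose shape variability is also the highest — deliberately the
hardest class, as amorphous debris is in reality). Generation is pure:
`(spec, side, seed)` determine every pixel.

The source domain for pretraining is a set of composite geometric/texture
classes (rings, polygons, crosses, dot grids, checkers, stripes, wedges
with flat/gradient/banded textures) rendered on the same background and
greyscale bands. It shares low-level statistics — edges, curvature,
texture, background — with the fossil benchmark while sharing no class
renderer, which is precisely the premise of cross-domain transfer.

What passing the desk-scale experiments shows: that the implementation's
transfer machinery works end to end — pretrained low-level features
measurably help when target data are scarce, and recognition improves
with training-set size. What it does not show: performance on real
microfossils. Synthetic renderings lack 3-D relief, depth-of-field blur,
specular luster, taphonomic deformation and inter-taxon confusability of
real residues, and the desk-scale image side (32 px network input) caps
attainable accuracy well below what 224-px inputs with natural-image
pretraining reach on real data. Reproducing the original study's accuracy
levels requires its deposited images and an externally supplied
natural-image checkpoint, both outside this package's self-contained
scope.

## Desk-scale study conditions

`run_transfer_benchmark()` fixes the package's standard desk-scale
protocol (all sizes chosen once as the package's own conditions):

* benchmark: 9 taxa × 70 images rendered at side 128; 20 per taxon held
  out as the fixed test set (180 test images);
* source domain: 16 classes × 20 images; pretraining at input side 32 for
  10 epochs, Adam, learning rate 1e-3, batch 16;
* fine-tuning: input side 32, 20 epochs, learning rate 1e-4, batch 16;
* transfer-vs-scratch comparison: TS fine-tuning versus the same
  architecture trained from random initialisation, 3 images per taxon,
  5 independent groups;
* learning curve: TS over sizes {1, 3, 5, 10, 50}, 3 groups per size.

The TS variant in this harness retrains `conv5_x` and the head. On the
real data the deepest-retraining TS variant (from `conv3_x`) was the
optimum; at desk scale the `conv5_x` variant is used because its long
frozen prefix makes the repeated-subsampling grid tractable on one CPU via
feature caching, and because with 32-px inputs and a small synthetic
source the earlier stages carry the transferable content. Augmentation is
off in the harness runs (it remains a first-class, tested pipeline
component; enabling it disables feature caching since each run then sees
different pixels).

Open choices resolved here, for the record: class order is lexicographic
by folder name; manifests are plain CSV; the unique test set is drawn
before augmentation; the checkpoint stores 64-bit floats because the
round-trip contract (bit-exact tensors) outranks file size at these model
sizes; and whether the last stage's dashed unit also downsamples spatially
is answered "yes", following the cited architecture.

## Known limitations

* CPU-only and deliberately small: a full 224-px, 1000-class pretraining
  run is far outside this implementation's performance envelope.
* No learning-rate schedules, weight decay, early stopping or validation
  splits — none are described in the source protocol, and the package
  keeps the training loop minimal and fully deterministic instead.
* The SVM baseline inherits `e1071`'s one-vs-one decision scheme rather
  than one-vs-rest; with the RBF defaults used here the distinction has no
  practical effect on the reported comparisons.
* Synthetic realism stops at silhouettes, greyscale texture and
  background; see above for what that implies about external validity.
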