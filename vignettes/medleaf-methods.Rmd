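---
title: "medleaf: models, design choices and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medleaf: models, design choices and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

Automated identification of medicinal plant species from leaf photographs is
a multi-class image-classification problem complicated by high visual
similarity between species and small, imbalanced labelled collections.
`medleaf` implements a complete framework for this task:

1. **Dataset balancing** by three bijective augmentations — horizontal
   mirror ("flip left"), vertical mirror ("flip right") and a 90° rotation —
   applied cyclically until every class reaches a target size.
2. **Two custom CNN feature extractors**: a residual-block stream and an
   inverted-residual-block stream, each ending in a global average pool
   (GAP) that emits a 1024-dimensional deep-feature vector per image.
3. **Serial feature fusion**: column-wise concatenation of the two streams'
   `N x 1024` matrices into one `N x 2048` matrix, with optional reduction
   by per-column histogram entropy.
4. **Binary Chimp Optimization (BCO)**: a wrapper feature selector driven by
   the Chimp Optimization Algorithm (ChOA), with continuous chimp positions
   mapped to 0/1 feature masks through a logistic transfer.
5. **Shallow neural-network classifiers** (narrow / medium / wide /
   bilayered / trilayered) scored by stratified 10-fold cross-validation on
   a pooled confusion matrix.
6. **Grad-CAM** heatmaps localizing the image regions that drive a class
   score.

Everything is testable offline: a parametric leaf-image generator and a
planted-signal feature-table generator stand in for external data.

## The two architectures

Both streams are expressed as typed layer graphs (`arch_graph`) over the
node vocabulary *input, conv, batchnorm, relu, grouped_conv, add, gap, fc,
softmax, classification*; every named node counts as one layer in the
census. Shape inference from a 224x224x3 input validates each graph, and
the realized networks (forward + backward passes over im2col/GEMM
convolution kernels) are checked against the graph's inferred shapes in the
tests.

**Residual stream** (`build_residual_net()`). A 3x3/16-channel/stride-2
stem; a depth-16 block of two parallel four-conv branches plus a 5x5 skip
convolution, merged by elementwise addition; a depth-32 block of two
parallel three-conv branches (stride-2 entry) with a 1x1 projection
shortcut; a chain of four 1x1 mixing convolutions; and a head in which a
grouped convolution (3x3, 2 groups, stride 2) expands 32 channels to the
1024 GAP channels, followed by FC, softmax and classification. The printed
constraints this design realizes are: 45 layer nodes, 22 of them
convolutional, a 1024-dim GAP feature, and a learnable-parameter total of
258,030 at 30 classes — i.e. 258k to the stated precision. The structural
knobs that are *not* printed anywhere (branch lengths, the 5x5 and 1x1
convolutions, the grouped-conv group count) were chosen once to satisfy all
four constraints simultaneously and are frozen; a total of exactly 258,000
is unreachable under any 16-multiple channel plan, because the FC layer
contributes 1024x30+30 = 30,750 ≡ 14 (mod 16) while every conv/BN block
contributes a multiple of 16.

**Inverted-residual stream** (`build_inverted_residual_net()`). The same
stem, then three inverted-residual blocks of output depths 16, 32 and 64:
each expands 2x through a 1x1 convolution, applies a grouped 3x3 spatial
convolution at the expanded width, and projects back through a 1x1
convolution, with a shortcut between the narrow ends (identity where shapes
allow, 1x1 projection otherwise). Block 3 uses pre-activation ordering (it
opens with ReLU); blocks 1–2 use post-activation. A grouped-conv head
expands 64 channels to the same 1024-dim GAP feature so the two streams
fuse symmetrically.

"Parallel blocks" merge by elementwise addition — the standard residual
semantics; no other merge operator is specified anywhere, and addition is
the only one consistent with the add-node shape rules.

Batch norm uses batch statistics during training and running statistics
(momentum 0.1, epsilon 1e-5) at inference; running statistics are not
counted as learnable parameters.

## Training protocol

`train_config()` defaults to the study protocol: SGDM, mini-batch 16,
learning rate 1e-4, 10 epochs. Momentum is 0.9 — the conventional SGDM
value; only the optimizer family is named in the protocol. The loss is
categorical cross-entropy after softmax (implied by the softmax /
classification head). No learning-rate schedule and no weight decay are
used, since none are specified. Training is fully reproducible given the
config seed, which controls initialization (He-normal) and batch order.

At this learning rate the network needs a reasonable number of optimizer
steps to fit even an easy task, so the separable fixture used in the tests
is sized accordingly: 3 classes x 60 images at high parameter separation,
64 px inputs, which gives the prescribed 10 epochs enough steps to exceed
90% training accuracy. That fixture size is a fixture design choice, not a
protocol change — the optimizer hyperparameters are never altered.

Images are bilinearly resized to the network input (224x224x3 by default;
the builders are input-size agnostic, and the synthetic studies run at
64 px where the same graphs remain valid). The train/test split is a
stratified half/half partition, fixed by seed. The split happens *before*
augmentation and only the training half is augmented: the alternative
(augment, then split) would leak near-duplicates of test images into
training. Augmented copies cycle deterministically through the three
primitive operators and then their dihedral compositions (7 distinct
non-identity grid bijections); beyond `7 x n_source` copies the cycle
repeats, with a warning.

## Serial fusion and entropy ranking

`serial_fuse()` concatenates the feature matrices column-wise — the only
reading of "serial" fusion consistent with the stated `N x (k1 + k2)`
output — and refuses misaligned rows (checked via record ids when present)
rather than truncating. Entropy ranking min-max normalizes each column,
histograms it into 256 equal-width bins (neither the discretization nor the
bin count is specified anywhere; 256 bins matches 8-bit intensity
resolution) and keeps the `keep` highest-entropy columns, ties broken by
lower column index, original column order preserved. The default is *no*
reduction (`keep` unset): whether entropy selection should reduce the fused
2048 back to 1024 is ambiguous in the source description, so reduction is
opt-in and the selected indices are always logged.

## ChOA / BCO conventions

The position update follows the four-leader scheme: for leader
`i ∈ {attacker, barrier, chaser, driver}` (the four best solutions of the
current population, in fitness order),

    D_i = | C_i · x_leader_i − m · x_chimp |,
    x_i = x_leader_i − A_i · D_i,
    x_chimp(t+1) = (x_1 + x_2 + x_3 + x_4) / 4.

The coefficients are used but not defined in the source description, so the
original ChOA conventions are adopted: `f` decays linearly from 2.5 to 0
over the iteration budget; `A = 2 f r1 − f` and `C = 2 r2` with fresh
uniform draws per chimp, per leader, per dimension; `m` follows a logistic
chaotic map (`m ← 4 m (1 − m)`) per chimp. The printed update omits the
absolute value in `D`; it is implemented *with* the absolute value
(distance semantics of the source algorithm), and `raw_distance = TRUE`
reproduces the literal printed form. `choa_step()` is verified to machine
precision against a deliberately naive loop transcription of the update on
100 random configurations.

The binary wrapper maps positions in `[−4, 4]` (logistic transfer values
0.018–0.982, so no bit is frozen) to masks via `bit = 1 iff rand < S(x)`
with a fresh uniform per bit per iteration; an all-zero mask is repaired by
setting the bit with the largest transfer value. The wrapper objective is

    fitness = alpha · (1 − CV accuracy) + (1 − alpha) · |mask| / d

with `alpha = 0.99` (the common accuracy-dominant wrapper default). The
inner classifier is 1-nearest-neighbour with 3-fold stratified CV. A
trained-MLP inner objective (the narrow preset) is available via
`fitness_classifier = "nnn"`, but 1-NN is the default: the wrapper
evaluates tens of thousands of masks across a selection study, 1-NN is the
standard inner objective in the binary-metaheuristic feature-selection
literature, and it is two orders of magnitude cheaper per evaluation at
equal recovery quality on the planted benchmark. Fitness values are
memoized by mask. Elitism keeps the best mask ever seen, which makes the
reported fitness trace non-increasing by construction. Defaults
`pop = 20`, `T_max = 50` are conventional swarm sizes; neither is specified
in the source description. Selection runs on train-split features only;
the resulting mask is then applied to test-split features.

## Classifier suite and metrics

The five presets mirror the standard shallow-network family the table
labels correspond to — NNN `[10]`, MNN `[25]`, WNN `[100]`, BNN `[10,10]`,
TNN `[10,10,10]` hidden ReLU units; the acronyms are never expanded in the
source, and the narrow/medium/wide/bi/trilayered reading is the only one
consistent with five NN-suffixed presets. They are trained by full-batch
gradient descent with momentum (lr 0.05, momentum 0.9, 300 epochs,
standardized inputs) — small deterministic fits appropriate for feature
matrices with a few hundred rows.

Cross-validation is stratified (fold assignment fixed by seed, not
specified in the source) and accumulates held-out predictions into a pooled
confusion matrix with rows = true class. Accuracy is `100·trace/total`;
precision and recall are macro-averaged (single reported values per
classifier imply *some* averaging; macro is the standard choice under class
imbalance); F1 is the harmonic mean of macro precision and macro recall;
`error = 100 − accuracy`; the false-negative rate is `100 − recall`.
Classes never predicted receive precision 0, with a message. The pooled
accuracy equals the sample-weighted mean of per-fold accuracies — an exact
identity asserted in the tests.

## The synthetic generators

**Leaf images.** Each class is a point in a five-parameter generative
space: silhouette elongation, margin serration frequency, vein angle, hue,
and texture noise. Silhouettes are a parametric polar curve (ellipse
modulated by a sinusoidal serration term) — few parameters and smooth
interpolation between classes; per-image jitter adds translation, rotation
and scale variation. The background is textured noise (coarse blotches plus
pixel noise), not flat color, so figure/ground is meaningful for Grad-CAM,
and foreground masks can be saved alongside the images. The default spec
grid has 30 classes, mirroring the study dataset's class count; a
`separation` dial scales inter-class parameter spread, and classification
accuracy is checked to be monotone in it. What these images do **not**
emulate: photographic nuisance (illumination, occlusion, background
clutter, viewpoint), intra-class biological variation beyond jitter, or
photorealistic texture. Passing tests therefore demonstrate that the
machinery is correct and the pipeline behaves as designed on controllable
structure — not that real-world accuracy figures transfer.

**Planted feature tables.** All columns are i.i.d. Gaussian noise; on the
informative columns class `c` receives a mean shift of
`effect_size · noise_sd · (c − 1)`, so "standardized mean shift" reads as
adjacent-class separation in noise-SD units. With effect 3 and noise 1,
per-column ANOVA F ranks all informative columns above all noise columns in
every one of 20 seeds, and the selector's recovery of the planted set is a
measurable quantity.

## Numerical choices and degenerate inputs

- Convolutions: im2col + GEMM (RcppArmadillo), "same" padding computed as
  in the usual ceil-division convention; strides carry all downsampling
  (the layer vocabulary has no pooling node other than the terminal GAP).
- Batch norm epsilon 1e-5; inference-mode backward (used by Grad-CAM)
  differentiates through the running-statistics affine form.
- A constant feature column has entropy 0 and is ranked last (ties by
  index); a constant image stays constant under bilinear resize; an
  all-zero input image produces finite features.
- Non-finite training loss aborts with a diagnostic rather than continuing;
  non-finite chimp positions are clamped to the box with a warning.
- Grad-CAM with zero gradient everywhere returns the all-zero map with a
  warning; otherwise the map is min-max normalized so its maximum is 1.

## Problem sizes used by the test suite

The synthetic studies are sized for a single CPU: the separable training
fixture is 3 classes x 60 images at 64 px; the end-to-end pipeline fixture
is 5 classes x 30 images at 64 px with 10-fold cross-validation over the
held-out half; the planted-recovery study is 20 seeds of a 300 x 50 table
with 5 informative columns (population 20, 40 iterations). The structural
checks on the residual stream run one 224 px input.

## Known limitations

- The self-attention stream mentioned once in the source overview is
  specified nowhere (no layer, shape or figure) and contradicts the
  two-stream description used everywhere else; it is not implemented.
- The two architecture descriptions overlap heavily; beyond the block
  count (two vs three), block depths and the pre-activation third block,
  the distinctions are design choices documented above.
- Training a 258k-parameter CNN from scratch for 10 epochs at lr 1e-4 on a
  few dozen images moves mostly the classifier head; the deep features at
  that scale are largely the initialization's random projections. This is
  sufficient for the separable fixtures and honest about what 10 epochs at
  that learning rate can do at desk scale.
- The headline accuracy tables of the source study require its external
  image collection and full-scale training; they are reported by this
  package only if a user supplies that data and are not asserted anywhere.
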