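---
title: "Fused compressed networks with self-normalizing heads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused compressed networks with self-normalizing heads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(endofuse)
```

## The model

`endofuse` builds a four-class classifier for gastrointestinal endoscopy
images (healthy mucosa, ulcer, polyps, esophagitis) that is deliberately
cheap to train: three well-known convolutional feature extractors are
*truncated* at fixed intermediate layers, frozen, fused, and topped with a
small self-normalizing trainable head.

**Compression by truncation.** Each backbone keeps only its prefix up to a
named cut-point layer; everything deeper is discarded:

| backbone        | cut-point          | cut shape (224 input) | parameters |
|-----------------|--------------------|-----------------------|------------|
| ResNet50V2      | `conv3_block3_out` | 28 x 28 x 512         | 1,171,456  |
| MobileNetV2     | `block_12_add`     | 14 x 14 x 96          | 558,656    |
| EfficientNetB0  | `block6d_add`      | 7 x 7 x 192           | 2,912,364  |

Parameter totals follow the mainstream convention: convolution kernels and
biases, dense weights, and four scalars per batch-norm channel (scale,
shift, moving mean, moving variance).  The builders reproduce the
reference layer definitions exactly — pre-activation bottlenecks with
max-pool shortcuts (ResNet50V2), inverted residuals with ReLU6 and
depthwise convolutions (MobileNetV2), and MBConv blocks with
squeeze-and-excitation gating, Swish, and stochastic-depth dropout
(EfficientNetB0) — so the totals above are reproduced to the scalar, and
each compressed graph is a strict prefix of the full architecture's layer
sequence (`backbone_manifest()`); the removed units number 2 / 4 / 1
stages or blocks respectively.  The backbones are frozen: weights
non-trainable *and* batch-norm statistics pinned (inference mode), the
standard transfer-learning treatment.

**Input resolution.** 224 x 224 x 3 is the only resolution at which the
three branches can be equalized by the published head arithmetic: the
branch spatial sizes are H/8 (after the head convolution, H/8 − 5, pooled
by 3), H/16 − 7, and H/32, and the equalization condition
H/16 − 7 = H/32 has the unique solution H = 224.  `assemble_model()`
therefore refuses shapes whose head arithmetic cannot align.

**Shape-equalizing auxiliary heads.** Each branch passes through
Conv(f = 192, kernel k, stride 1, valid) → AveragePool(p, valid) → alpha
dropout (rate 0.2), with (k, p) = (6, 3), (8, 1), (1, 1) for the ResNet,
MobileNet and EfficientNet branches, mapping all three to exactly
7² x 192 by the valid-padding recurrence floor((n − k)/s) + 1.  The
convolutions are SeLU-activated and LeCun-normal initialized, keeping the
heads inside the self-normalizing regime.

**Fusion.** The equalized branches are fused channel-wise to 7 x 7 x 576.
A literal elementwise summation is also available
(`assemble_model(fusion = "add")`), but concatenation is the default: it
preserves the identity of each branch's features and it is what makes the
residual block's 1 x 1 projection necessary at all (576 in, 192 out).

**Modified residual block.** The fused map x is refined by

y = F(x, {W_i}) + W_q x,  F = W_n · SeLU(BN(W_1 · SeLU(BN(x))))

two pre-activation stages (BN → SeLU → Conv 3 x 3) plus a learned 1 x 1
projection W_q that equalizes channel counts so the addition is
well-formed.  W_1 carries no bias (a batch-norm follows it); W_n and W_q
do.  With width 192 the three convolutions hold exactly 1,438,080
scalars.  No dropout lives inside the block — regularization is placed in
the auxiliary heads and classifier only.  Width 192 mirrors the fusion
budget of the heads; kernel sizes 3/3/1 and stride 1 preserve the 7 x 7
grid.

**Classifier.** Global average pooling → alpha dropout (0.2) → dense
softmax.  The head is intentionally minimal.  The final dense layer is
initialized near zero (sd 1e-4): fused features arrive at a scale that
depends strongly on the frozen backbones, and a fan-in-scaled
initialization can start the softmax saturated, stalling short training
runs; a near-uniform initial softmax is the standard cure and is
scale-robust.  All other trainable layers keep the SeLU/LeCun-normal
pairing.

## Self-normalization

The scaled exponential linear unit is

SeLU(x) = λx for x > 0, λα(eˣ − 1) for x ≤ 0,

with the fixed-point constants α = 1.6732632423543772,
λ = 1.0507009873554805 (4-decimal prints: 1.6733, 1.0507).  Its negative
saturation is α′ = −λα ≈ −1.7581.  With LeCun-normal weights
(sd = 1/√fan_in; the package uses the two-sigma truncated variant,
variance-corrected, switchable to the plain normal) a stack of SeLU layers
drives activations toward zero mean and unit variance — the property the
test suite checks empirically on a 10-layer stack of width 64 with 10⁵
standard-normal inputs, against a ReLU control that drifts.

Alpha dropout replaces dropped units with α′ rather than zero and applies
the affine correction a·x + b with

a = (q + α′² q (1 − q))^(−1/2),  b = −a (1 − q) α′,  q = 1 − rate,

which restores the first two moments of standard-normal input in
expectation.  The default rate is 0.2 everywhere dropout appears.

## Training

Defaults (`train_config()`): batch size 8, 25 epochs, Adam at learning
rate 1e-5 (β₁ = 0.9, β₂ = 0.999, ε = 1e-7), pixels rescaled by 1/255.
The categorical cross-entropy, mean over observations of
−Σ_c Y_{o,c} log P_{o,c}, clips probabilities at 1e-7 before the
logarithm.  A reduce-on-plateau schedule watches an accuracy metric
(validation accuracy by default, training accuracy when no validation
split is supplied — both readings are supported because either is a
defensible monitored quantity): strict improvement resets a counter;
after 2 non-improving epochs the rate halves, never below 1e-6.  From
1e-5 under a never-improving metric the trace is exactly
1e-5, 5e-6, 2.5e-6, 1.25e-6, 1e-6.

**Batch-norm re-estimation.** An architectural subtlety deserves note:
the auxiliary heads end in (alpha) dropout, and the next learnable layer
— the residual block's first batch-norm — therefore gathers its running
statistics from dropout-active activations, which are affinely rescaled
relative to what dropout-free inference produces.  On inputs that are far
from standardized (frozen randomly initialized backbones produce channels
with large mean-to-spread ratios) the resulting shift reaches several
standard deviations per channel and can collapse inference predictions
entirely, even when training-mode accuracy is high.  `train()` therefore
re-estimates the head's batch-norm buffers after every epoch from forward
passes run with batch statistics but dropout disabled (a bounded
subsample of the training features) — the classic batch-norm
re-estimation procedure.  Head batch-norms also use momentum 0.9 so
running statistics converge within short runs.  Neither choice alters the
architecture or its parameter counts.

Augmentation (training split only, config-driven, off by one flag):
horizontal/vertical flips, rotations within ±15°, shifts within ±10%,
nearest-neighbour resampled with edge clamping — mild and
label-preserving.  When every backbone is frozen and augmentation is off,
`train()` precomputes each image's branch features once and trains the
head on the cache; this is the classical bottleneck-feature shortcut and
is mathematically identical to the naive loop.

## Evaluation

Multi-class accuracy is correct/N.  Per-class precision TP/(TP+FP),
recall TP/(TP+FN) and F1 (harmonic mean) are aggregated
support-weighted by default (on balanced splits weighted recall then
equals accuracy, a useful cross-check) with macro averaging available;
zero-denominator classes score 0 with a warning.  One-vs-rest per-class
accuracies are reported in `tidy()` for transparency.  The ablation
driver (`run_ablation()`) crosses the residual block (together with its
SeLU/LeCun pairing) with the dropout kind {alpha, standard, none} — six
variants sharing frozen backbones and seed, so rows differ only in the
layers under test.

## The synthetic corpus

`generate_dataset()` emulates the curated corpus layout — 800/500/200
images per class per split, totals 3,200/2,000/800 — with four visually
separable classes on a mucosa-like textured background: a bright raised
blob (polyps), a pale crater with a dark rim (ulcer), bright longitudinal
streaks (esophagitis), plain texture (normal), all with jittered
position, size and intensity plus pixel noise.  Image generation is keyed
by (seed, split, class, index), so regeneration is byte-identical and no
image can leak across splits.  Scaled-down corpora floor the counts with
a minimum of 2 per cell.

What passing tests on this corpus do and do not show: the classes are
honestly learnable but far easier than endoscopy photographs — no
specular highlights, instrument artefacts, viewpoint or illumination
extremes, and the class signatures are unimodal.  Success here validates
the plumbing (shapes, gradients, schedule, metrics) and the learnability
of the architecture, not clinical performance; headline accuracies from
the curated corpus require the real data and full training and are out of
scope.

## Numerical choices and problem sizes

* Convolution/pooling kernels run in float32 (im2col + BLAS GEMM), the
  working precision of mainstream deep-learning frameworks; everything
  else is double.  Finite-difference tests therefore use step 1e-3.
  The kernels enable flush-to-zero/denormals-are-zero locally (restored
  on exit): converged training produces float32-denormal gradients whose
  hardware arithmetic is orders of magnitude slower, and flushing them is
  the established framework practice.
* Batch-norm epsilons follow the reference architectures (1.001e-5 for
  the pre-activation ResNet, 1e-3 elsewhere); momentum 0.99.
* Backbones initialize He-normal (they are frozen; counts and shapes are
  weight-independent).  An optional hook loads pretrained weights from an
  RDS of named arrays; nothing in the tests requires it.
* Because a randomly initialized backbone would freeze with placeholder
  (0, 1) batch-norm statistics — leaving per-channel feature scales
  spanning orders of magnitude, unlike the well-scaled features a
  pretrained network emits — `assemble_model()` first calibrates every
  backbone batch-norm's moving moments on a deterministic probe batch,
  layer by layer (`calibrate_backbone()`), and then freezes.  This
  restores the regime the architecture assumes without touching weights,
  counts or shapes.
* Desk-scale runs in the test suite train on the 5% corpus (40 train
  images/class at 224², batch 8, 10 epochs) and a 12-per-class 3-epoch
  grid for the ablation.  These runs use learning rate 1e-3 rather than
  the 1e-5 default: the default was tuned for ~10,000 Adam steps on the
  full corpus, while the desk-scale budget is ~200 steps, two orders of
  magnitude fewer; scaling the rate keeps total parameter movement
  comparable.  The 1e-5 default itself is untouched.
* Ties in the plateau schedule count as no improvement (strict `>`), and
  the first epoch always "improves" over the initial −Inf.
* FLOPs are reported, never asserted, as 2·MACs over convolution and
  dense kernels only (biases, batch-norm, activations excluded), stated
  in every cost report because published figures for fused models vary
  with unstated conventions.

## Known limitations

* Forward-pass numerical parity with any external implementation is not
  a goal; architecture fidelity is defined by layer sequence, shapes and
  parameter counts, which are asserted exactly.
* Backward passes exist only for the trainable head kinds; frozen
  backbones are never backpropagated through (so `augment = TRUE`
  fine-tuning of backbones is out of scope, as is unfreezing).
* The pure-R/BLAS engine is single-threaded and CPU-bound; it is sized
  for the desk-scale corpus, not for full-scale training.
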