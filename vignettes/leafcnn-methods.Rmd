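---
title: "Lightweight channel-attention networks for leaf disease images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight channel-attention networks for leaf disease images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Recognising crop leaf diseases from field photographs is a fine-grained,
cluttered-background image classification task: lesions are small, sparsely
distributed, and often differ between classes only in spot count, size and
hue, while the background (soil, other foliage, lighting) varies freely and
carries no label information. Models intended for deployment near the field
must additionally be small. `leafcnn` implements a lightweight
ShuffleNetV2-family convolutional architecture specialised for this setting,
together with the complete experimental harness around it: data splitting
and augmentation, the training recipe, the evaluation suite, robustness
perturbations, and a synthetic image generator that makes the whole pipeline
testable on a desktop with no external data.

Everything, including the convolution/backpropagation engine itself, is
implemented in the package (R with Rcpp kernels for the convolution and
pooling loops, BLAS for the matrix products). Activations use the
channel-first layout `dim = c(C, H, W, N)`.

## The backbone

The network follows the standard ShuffleNetV2 skeleton: a stride-4 stem to
24 channels, three stages each opening with one downsampling unit followed
by a run of *basic units*, a final pointwise convolution, global average
pooling and a linear classifier. On a 224 px input the spatial trajectory is
224 → 56 → 28 → 14 → 7.

A **basic unit** splits its \(C\) channels into halves; the left half passes
through untouched while the right half runs 1×1 conv → BN → ReLU → 3×3
depthwise conv → BN → 1×1 conv → BN → ReLU, followed by channel attention.
The halves are concatenated and a channel shuffle with two groups interleaves
them (position \((g, i)\) of the group grid moves to \((i, g)\)), which is
what lets information cross the split over depth. A **downsampling unit**
has no split: both branches run at stride 2 and concatenate to the stage
width.

Two structural options are layered on this skeleton:

* **Residual shortcuts** (`residual = "rm" | "ra" | "rc"`). In basic units
  the unit input is added to the shuffled output (identity shortcut, no
  extra activation after the add — the add sees the unit's final output).
  In downsampling units the shortcut must change resolution and width:
  `rm` uses 3×3 max pooling (stride 2) followed by a 1×1 convolution + BN,
  `ra` the same with average pooling, and `rc` a strided 3×3 convolution +
  BN. Pooling is parameter-free, so `rm` and `ra` cost identical parameters
  and `rc` is strictly heavier — an invariant the tests pin down.
* **Channel attention** (next section), applied at the tail of the pointwise
  convolution of each unit's transform branch — in the downsampling unit it
  sits on the convolutional branch, mirroring the basic unit's placement.

The flagship preset (`leafnet_config()`) uses repeats `[2, 3, 2]` and
channels `[96, 192, 384, 1024]` — a deliberately slimmer layout than the
standard `[3, 7, 3]` / `[116, 232, 464, 1024]` of ShuffleNetV2-1.0, which is
also constructible (`shufflenet_config()`) along with the full tuning grid
between them. `repeats` counts basic units only; every stage is always
opened by exactly one downsampling unit, which is the reading under which
the standard network appears as `[3, 7, 3]` in the same grid.

### Dual-pool channel attention

For an activation \(X \in \mathbb{R}^{H \times W \times C}\), each channel
\(c\) is summarised by its spatial mean and population standard deviation

\[
A_c = \frac{1}{HW}\sum_{h,w} X_c(h,w), \qquad
S_c = \sqrt{\frac{1}{HW}\sum_{h,w}\bigl(X_c(h,w) - A_c\bigr)^2},
\]

(the divisor is \(HW\), so a spatially constant channel has \(S_c = 0\)
exactly). Each C-vector is convolved along the *channel axis* by its own
bias-free 1-D kernel of odd length \(K\) (zero padding \(\lfloor K/2
\rfloor\)), the two paths are summed, and a sigmoid produces one weight per
channel:

\[
\omega = \sigma\!\bigl(\mathrm{C1D}_K(y_1) + \mathrm{C1D}_K(y_2)\bigr),
\qquad Y_c = \omega_c X_c .
\]

The kernel size adapts to the width of the layer,

\[
K = \left| \frac{\log_2 C}{\gamma} + \frac{b}{\gamma} \right|_{\mathrm{odd}},
\qquad \gamma = 2,\; b = 1,
\]

so e.g. \(C = 96 \mapsto K = 3\) and \(C = 1024 \mapsto K = 5\). Rounding
follows the established ECA convention — truncate, then bump even values to
the next odd — which agrees with "nearest odd" everywhere on power-of-two
widths and resolves exact ties (such as \(C = 128\), argument 4.0) upward;
the nearest-odd rule is kept as an independent oracle in the tests. The two
path kernels are independent rather than shared: with a shared kernel the
two paths could not be weighted differently, and the learned kernels are
exactly what adapts the path mix. No additional scalar mixing coefficients
exist in the weight equation, so none are added. Each insertion therefore
costs exactly \(2K\) parameters — about 70 parameters across a whole model,
which is why attention leaves the parameter count essentially unchanged.

The comparators used in ablations are implemented behind the same interface:
**SE** (global average pool → bottleneck of reduction 16 → sigmoid; the
reduction default is the community standard), **ECA** (the average-pool path
alone), and **SRM**-style recalibration (per-channel linear combination of
the (avg, std) style vector → sigmoid). All preserve shape and produce
weights strictly inside \((0,1)\); on spatially constant input the std path
vanishes and the dual-pool operator collapses exactly to ECA — both facts
are tested.

### Multi-scale blocks and stems

All stems map RGB input to 24 channels at stride 4 (the ShuffleNetV2 stem
width; fixing it makes every stem drop-in interchangeable): `"a"` is 3×3
stride-2 conv + 3×3 stride-2 max pool, `"b"` the same with a 7×7 conv,
`"c"` stacks three 3×3 convolutions before the pool. The multi-scale
shallow stem (`"msfem"`) feeds a shared 3×3 stride-2 convolution into two
branches — a 3×3 stride-2 max pool, and two stacked 3×3 convolutions with
the second at stride 2 — concatenated and fused by a 1×1 convolution. The
published figure for this block is schematic, so branch widths (16 + 16
fused to 24) are the package's own choice, selected to keep the stem small
while remaining the largest of the four; only the parameter *ordering*
MSFEM > C > A and the near-equality of A and B are asserted, never absolute
counts.

The deep multi-scale block (`mdfem = TRUE`) sits between Stage4 and the
final pointwise convolution (the description says only "deep"; after the
last stage is the only placement that leaves stage shapes untouched): two
parallel same-padding branches — 3×3 and 5×5 convolutions, each to half the
input channels — concatenated and fused back to the input width by a 1×1
convolution.

Batch normalisation follows every convolution; ReLU only where the
reference unit diagrams place it (in particular, not after depthwise
convolutions).

## Training recipe

`train_config()` defaults encode the standard recipe for this architecture
family: batch size 32, 60 epochs, SGD with momentum 0.9 and weight decay
5e-4, initial learning rate 0.01 annealed by

\[
lr(t) = lr_{\min} + (lr_0 - lr_{\min})\frac{1 + \cos(\pi t / T)}{2}
\]

to a floor of 1e-9 at \(t = T\). The schedule is stepped once per epoch
("total number of steps in a cycle" equal to the epoch count), and the
recorded sequence hits both endpoints exactly and decreases monotonically.
Weight decay applies to convolution and linear weights (including the
attention kernels) but not to batch-norm parameters or biases — standard
practice. Inputs on the 0-255 scale are normalised per channel with fixed
constants (mean 127.5, sd 60) recorded in the configuration. Initialisation
is seeded He-normal; no pretraining is used. The best-accuracy epoch's
weights (parameters *and* batch-norm running statistics) are checkpointed,
and restoring them reproduces the recorded accuracy bit for bit.

"Iterations = 60" is read as 60 epochs, matching training curves plotted
per round.

## Data pipeline

* **Split.** The 8:2 train/test split draws `floor(0.2 * n)` items per
  class uniformly at random. The floor rule is the unique rounding
  consistent with all 22 printed (train, test) pairs of the reference
  22-class manifest shipped in `leaf_disease_manifest()`, and the tests
  reconstruct every pair from the per-class totals.
* **Expansion.** Per-class augmentation factors are integer data from the
  manifest (`n_augmented = factor * n_original` holds for every class; no
  closed-form rule reproduces them — one class stops at 894 rather than
  being pushed to ~1000 — so they are recorded, not computed). Each
  original yields itself plus `factor - 1` variants, chosen by
  deterministically cycling an op list offset by the image index under the
  run seed.
* **Augmentation plan** (exact parameters unstated in the source material;
  fixed here once): brightness × 1.3 and × 0.7 with clipping to [0, 255],
  right-angle rotations (90°, 180°, 270°), horizontal and vertical flips,
  and free rotation within ±30°. Rotation is bilinear about the centre with
  reflective boundary fill, implemented in-package because the available
  image libraries fill rotations with a constant colour, which would leak a
  trivial augmentation signature into corners.
* **Robustness perturbations**: Gaussian pixel noise (default σ = 25 on the
  0-255 scale), rotations of 15°/30°, and brightness factors 0.6 / 1.4 for
  the decreased/increased treatments — defaults chosen once where the
  source is silent. Noise obeys the folded-normal identity (mean absolute
  change σ√(2/π) on mid-gray), which the tests verify.

## Evaluation

Per class (one-vs-rest): \(P = TP/(TP+FP)\), \(R = TP/(TP+FN)\),
\(F1 = 2PR/(P+R)\), with 0/0 defined as 0 (a warning is emitted). Headline
accuracy is trace/total of the confusion matrix; the one-vs-rest accuracy
\((TP+TN)/\text{total}\) is exposed per class but never aggregated, since
summing it over classes inflates the value. Aggregation is **macro**
(unweighted class means) — chosen because reported F1 typically differs
from accuracy under macro averaging on mildly imbalanced test sets —
with support-weighted means also returned for comparison. Per-crop
summaries are macro within each crop's member classes (7/3/4/2/3/3 classes
for the six crops of the reference manifest). The whole suite is verified
against a brute-force per-sample tally and against an independent
implementation (caret) in the tests.

## The synthetic generator

`synth_spec()` / `generate_dataset()` emulate the *structure* of a field
leaf-disease dataset: a cluttered background (random colour blobs + grain),
an elliptical green leaf with jittered pose and texture, and class-specific
lesion spots whose count, radius and hue are drawn from per-class ranges;
every spot lies entirely inside the leaf ellipse. Background and leaf
statistics are drawn from the same distribution for all classes, so the
label signal lives only in the lesions; the tests check this by comparing
background statistics across classes (full train-under-label-shuffle
experiments would re-run minutes of training for a property the
construction already guarantees, so the cheap statistical check is used
instead). The default study conditions — 4 classes (healthy + three lesion
types with disjoint parameter ranges in the `"easy"` setting), 100 train /
25 test per class, 64 px — were fixed up front as a desk-scale analogue;
`"hard"` overlaps the ranges to make classes genuinely confusable.
Generation is a single seeded stream: identical spec + seed regenerates
bit-identical arrays, and written PNG folders round-trip losslessly.

What passing does and does not show: the synthetic images have none of the
photometric variability, occlusion, scale range or inter-class subtlety of
field photographs, so the learning-sanity result demonstrates that the
architecture, gradients, optimiser and pipeline work end to end — not that
field-level accuracy is reproduced, which would require the original
private dataset and GPU-scale training.

## Numerical choices

* Batch norm uses population variance with ε = 1e-5 and momentum 0.1 on
  running statistics; evaluation mode uses the running estimates.
* The std-pool backward guards the division by σ with a 1e-12 floor; at
  σ = 0 the numerator vanishes identically so the gradient is exact.
* Max pooling treats padding as −∞ and breaks ties by first index; its
  backward scatters to the argmax.
* 1-D channel convolutions are cross-correlations with zero padding
  `K %/% 2`, so the output length always equals C.
* Cross-entropy clamps probabilities at 1e-12 before the log.
* All backward passes are verified against central finite differences at
  tolerance 1e-6 per module, and gradient flow through the full flagship
  preset is smoke-tested (every parameter receives a finite gradient; stem
  gradients are non-zero).

## Problem sizes in the shipped tests

The test and acceptance runs use the reduced preset
(`tiny_leafnet_config()`: channels `[24, 48, 96, 256]`, repeats
`[1, 1, 1]`) at 64 px with the 4-class easy synthetic set (500 images,
10 epochs) — sizes chosen so the entire suite runs in a few minutes on one
CPU while still exercising every architectural component, including both
multi-scale blocks, attention and residual shortcuts. The flagship preset
is built and counted (~3.55 M parameters) but not trained in the tests.

## Known limitations

* The engine is CPU-only and optimised for clarity at desk scale; training
  the flagship preset on a real 20k-image dataset is out of its intended
  range.
* Absolute parameter totals are not comparable to published "Parameters/M"
  columns for this architecture family, whose figures are schematic about
  branch widths (and internally inconsistent between parameter and
  model-size columns); the package asserts orderings and exact deltas
  instead.
* JPEG input is not supported (PNG only) — the synthetic pipeline and all
  fixtures are PNG; plug in any decoder that yields `c(H, W, 3)` arrays on
  the 0-255 scale.
* The SRM comparator omits the original's batch-norm stage on the style
  vector, using the simpler linear-then-sigmoid form.
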