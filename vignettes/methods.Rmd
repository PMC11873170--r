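---
title: "Methods: nested segmentation-informed tongue shape classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested segmentation-informed tongue shape classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tongue shape — thin, normal or bulgy — is a diagnostic feature in
traditional Chinese medicine, and automating its classification is hard for
three reasons: tongues of the same class vary a lot between individuals, the
lips surrounding the tongue share texture and hue with the tongue body and so
act as a structured distractor, and clinical datasets are small (hundreds of
images). The approach implemented here attacks the problem by *nesting* a
segmentation network inside a classification network, so that the classifier
sees both where the tongue is and what the segmentation encoder learned about
it.

## The model

**RCA-UNet** is a four-stage U-Net for binary tongue/background
segmentation. Every encoder stage is a *dual convolution* (two successive
3×3 conv → batch-norm → ReLU layers) followed by a residual attention block,
then 2×2 max pooling; the bottleneck doubles channels a fourth time
(widths `base_width * c(1, 2, 4, 8)` with a `16 * base_width` bottleneck). The
decoder mirrors the encoder with 2×2 stride-2 transposed convolutions, and
each skip connection passes through a *multiscale attention gate* before
concatenation. A 1×1 convolution emits two logit channels per pixel;
the predicted mask is the per-pixel argmax and the training loss is mean
pixel-wise softmax cross-entropy.

**RCBAM** (residual convolutional block attention module) computes channel
attention (sigmoid of a shared two-layer bottleneck applied to the
global-average and global-max channel descriptors, summed) and spatial
attention (sigmoid of a 7×7 convolution over the channel-mean and
channel-max planes), and applies them multiplicatively around a residual:
`y = x + (x · CAM(x)) · SAM(x · CAM(x))`. With gates saturated at 1 the block
doubles its input; at 0 it is the identity, so the residual path always
preserves the signal.

**MSAG** (multiscale attention gate) runs three parallel convolutions —
pointwise 1×1, ordinary 3×3, and dilated 3×3 (dilation 2 by default) —
concatenates them, batch-normalizes and rectifies, and reduces the stack
with a 1×1 "vote" convolution to a single per-pixel sigmoid gate `g`; the
gated skip is `x + x · g`.

**RCA-Net** is the classifier: five conv blocks (3×3 conv → BN → ReLU →
RCBAM), the first two dilated with factors 3 and 2 so the stem sees 7- and
5-pixel spans without pooling; max pooling after blocks 2–5; a parallel
branch (RCBAM → max-pool → 1×1 projection) taps the block-1 output and is
added to the main path at the post-block-2 resolution; adaptive average
pooling to 1×1 feeds a 512–512–3 fully connected head with ReLU and dropout
(rate 0.5) between layers.

**IF-RCNet** couples the two networks twice. *Mixed input*: the
segmentation foreground probability is appended to the RGB image as a fourth
input channel (default; a six-channel masked-RGB-concat variant exists).
*Feature fusion*: one encoder feature map (the bottleneck by default) is
projected by a 1×1 convolution to 128 channels, global-average-pooled, and
concatenated before the classifier's first FC layer. Training is two-phase
by default: the segmentation network is trained to convergence, frozen, and
the classifier is trained on top; joint fine-tuning through the soft mask is
available behind `freeze_seg = FALSE`.

## Design choices where the architecture description is open

Several details are not pinned down by the published description; the
package resolves them as follows and exposes each as configuration:

* **CAM/SAM internals** follow the standard convolutional block attention
  construction (shared bottleneck with reduction 16; 7×7 spatial kernel),
  applied sequentially (channel first), with one residual around the whole
  composition.
* **"Vote" convolution** is read as a 1×1 convolution from the 3C
  concatenated channels to a single channel followed by a sigmoid — the
  common attention-gate construction.
* **Skip merge** is concatenation of the gated skip with the upsampled map,
  the standard U-Net choice; encoder widths double per stage since none are
  published.
* **Classifier widths** default to (32, 64, 128, 256, 512) so the pooled
  feature is 512-dimensional, matching the 512-node head naturally.
* **Branch merge** is elementwise addition after a 1×1 projection to the
  block-2 width (a projection is dimensionally required; no merge rule is
  published).
* **The dilation/receptive-field discrepancy**: the published text says the
  dilated stem reads 6×6 and 5×5 pixel regions, but a 3×3 kernel at
  dilation 3 spans 7 pixels and at dilation 2 spans 5. The stated dilation
  factors are followed; the span arithmetic is asserted in tests.
* **Optimizer**: the training description names both Adam (learning rate
  0.0001) and SGD. Adam is the default because it carries the explicit
  learning rate; SGD remains available.
* **Evaluation subset**: the 20% subset is used as a validation set for
  best-epoch selection, and test metrics are computed exactly once per round
  on the 10% test shard.
* **Fusion point**: vector-level concatenation before the first FC layer,
  from the deepest encoder stage ("the coding layer" is singular in the
  source description); multi-stage spatial fusion is out of scope.

## Cross-validation protocol

The dataset is shuffled once under a seed and split into 10 near-equal
shards, stratified by class when labels are available (unstratified 10%
shards of a small dataset can miss a class entirely). Round *r* (0–4) takes
shard 2*r* as the 10% test subset and the next two shards cyclically as the
20% evaluation subset, leaving 70% for training — the 3.5 : 0.5 : 1 ratio.
Test shards are therefore pairwise disjoint across rounds; evaluation
subsets may overlap between rounds. Per-round metrics are averaged
arithmetically.

## Metrics

Classification: accuracy, one-vs-rest precision and recall, per-class F1 =
2PR/(P+R), macro (unweighted) F1 over the three classes, and the 3×3
confusion matrix. A zero denominator reports 0 with a warning rather than
failing, so reports stay total on degenerate shards.

Segmentation: per image, IoU is computed for background and foreground and
averaged (binary masks have k+1 = 2 categories); Dice = 2TP/(FN+2TP+FP); the
Hausdorff distance is the symmetric sup-inf distance between foreground
boundary pixel sets (4-connectivity erosion difference, Euclidean metric),
computed either by an O(|A||B|) brute-force reference or by an exact
Felzenszwalb distance-transform fast path — the two agree exactly on integer
grids and both are exposed. Dataset scores are means over images ("mean
Hausdorff distance" is read as the dataset mean of per-image symmetric
distances; a directed-mean variant is available as `hd_variant = "average"`).
Degenerate masks are defined so metrics stay total during early training:
both-empty scores IoU = Dice = 1 and HD = 0; exactly-one-empty scores Dice 0
and HD equal to the image diagonal.

## The synthetic scene generator

Real clinical images are not redistributable, so the package generates its
own benchmark scenes that preserve the *structure* of the problem: three
shape classes separated by tongue width, a lip distractor touching the
tongue boundary with a hue deliberately close to the tongue's, and
pixel-accurate masks. The tongue is a rotated super-ellipse (exponent 2.5)
whose lower half is stretched by a droop factor; class widths default to
0.35 / 0.55 / 0.80 of the image width (±5% jitter) — the published material
gives no geometric definition of thin/normal/bulgy, so these ratios are a
documented stand-in chosen to make the classes visually distinct yet
adjacent. The lip is a crescent band hugging the upper tongue boundary,
with hue pulled 80% of the way toward the tongue hue by default. Smooth
multiplicative texture (low-frequency sinusoids, amplitude 0.15) and
additive Gaussian noise (sd 0.03 in 0–1 intensity units) perturb the image
only — never the mask. Intensities are quantized to 8-bit levels so
in-memory arrays equal their PNG round-trips. Per-sample seeds derive from
the master seed as `(seed * 1e6 + index) mod (2^31 - 1)`, making every
dataset reproducible from one integer. An optional imbalance mode
redistributes counts to the 253/226/331 (thin/normal/bulgy) proportions of
the published 800-image dataset.

What the generator deliberately does *not* emulate: photorealistic texture,
illumination and camera effects, intra-class anatomical variation beyond
jitter, or annotation noise. Passing tests on these scenes demonstrates that
the architecture, optimization, bookkeeping and metrics are correct and that
the couplings help when a boundary-hugging distractor is present — not that
clinical-grade accuracy transfers to real tongues.

## Numerical and engineering notes

Feature maps are R arrays in (batch, channel, height, width) layout. All
layers implement explicit forward and backward passes; convolutions are
lowered via C++ `im2col`/`col2im` to BLAS matrix products, and every backward
pass is verified against central finite differences in the test suite.
Batch normalization uses biased batch variance for normalization, unbiased
updates for the running statistics (momentum 0.1, epsilon 1e-5), and running
statistics in evaluation mode — which is what makes the scalar oracles in
the tests well-defined. Max-pool ties break deterministically in a fixed
scan order; the mask argmax breaks ties toward background. Weight
initialization is Kaiming-scaled Gaussian from R's seeded RNG; everything
(initialization, shuffling, dropout) derives from the run seed, so CPU runs
are bit-reproducible.

Training defaults follow the published protocol (batch 2, Adam, learning
rate 1e-4, cross-entropy losses). The `"desk"` preset (batch 8, learning
rate 1e-3, 10 epochs) is the package's own scaled-down configuration for
CPU-sized synthetic runs, with early stopping (patience on the evaluation
metric) and best-epoch checkpointing.

Desk-scale problem sizes used by the test suite and the acceptance script,
chosen once as what a single CPU core handles in minutes: segmentation
trainability on 60 scenes at 64×64 with base width 16 (≤ 200 optimizer
steps); nested-classifier trainability on 150 samples at 64×64 with widths
(8, 16, 32, 64, 64); the coupling ablation on 90 lip-contact scenes at 48×48
with the same widths and three classifier epochs per configuration. At that
scale the per-round accuracies are high-variance (about nine test images per
round); only the direction of the mixed-input/feature-fusion effect averaged
over five rounds is claimed, never magnitudes, and individual seeds can
still land on the wrong side of the average.

## Known limitations

Joint fine-tuning backpropagates through the mask-channel coupling and the
fused encoder stage, but not through the six-channel masked-RGB coupling.
The headline percentages published for the clinical and BioHit datasets are
not reproducible here by design: they require those datasets and GPU-scale
training. The generator's width-ratio class definition is a stand-in, and
results on it say nothing about inter-annotator disagreement or acquisition
variability in real data.
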