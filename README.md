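# ifrcnet

Tongue shape — **thin**, **normal** or **bulgy** — is a diagnostic feature in
traditional Chinese medicine, and classifying it automatically is hard:
tongues of one class vary between individuals, the lips hugging the tongue
share its hue and texture and act as a structured distractor, and clinical
datasets are small. `ifrcnet` implements a two-level *nested* network for
this problem, in pure R (with C++ convolution kernels):

* **RCA-UNet** — a four-stage segmentation U-Net whose encoder stages carry
  residual channel+spatial attention (RCBAM) and whose skip connections pass
  through multiscale attention gates (MSAG: pointwise + 3×3 + dilated
  branches, batch-normalized, reduced by a 1×1 "vote" convolution to a
  per-pixel sigmoid gate `g`, output `x + x·g`).
* **RCA-Net** — a five-block dilated convolutional classifier (dilations
  3, 2, 1, 1, 1; RCBAM in every block; an RCBAM+max-pool branch; adaptive
  average pooling; a 512–512–3 fully connected head with dropout).
* **IF-RCNet** — the nesting of the two: the predicted tongue mask joins the
  image as a fourth input channel (*mixed input*), and pooled encoder
  features of the segmentation network are concatenated before the
  classifier's first FC layer (*feature fusion*):

  `logits = RCA-Net([image, mask], fused = pool(proj(RCA-UNet_enc(image))))`

Because the clinical datasets are not redistributable, the package ships a
deterministic synthetic scene generator (super-ellipse tongues whose width
separates the three classes, pixel-accurate masks, and a lip crescent whose
hue is pulled toward the tongue's), so every stage — training included — is
testable on a desk CPU. Segmentation is scored by mean IoU over
background+foreground, Dice `2TP/(FN+2TP+FP)`, and the mean symmetric
Hausdorff distance between mask boundaries; classification by accuracy and
macro F1. Evaluation uses a five-round rotating cross-validation with
70/10/20 (3.5 : 0.5 : 1) train/test/eval splits and disjoint test shards.

All network layers, backpropagation and the Adam/SGD optimizers are
implemented in the package itself (R arrays + BLAS, `im2col`/`col2im` and an
exact Euclidean distance transform in C++); every backward pass is verified
against finite differences, and every metric against brute-force oracles.

## Worked example

```r
library(ifrcnet)

# 60 synthetic 64x64 scenes, 20 per class, with lip distractors
scenes <- make_dataset(20, synth_scene(image_size = 64, seed = 11))

# train the segmentation network (base width 16, best-epoch selection)
seg <- fit_rca_unet(scenes, seg_config(base_width = 16),
                    train_config(preset = "desk", seed = 11, max_steps = 200))
print(seg)
#> RCA-UNet fit: base width 16, 60 steps, held-out Dice 0.9925

# score predicted masks against the generator's ground truth
masks <- predict(seg, scenes)
print(seg_metrics(masks, lapply(scenes, `[[`, "mask")))
#> segmentation report (n = 60): MIoU 0.9914, Dice 0.9939, MHd 1.017 px
```

Held-out Dice 0.99 means the network reproduces the generator's
pixel-accurate tongue masks almost exactly after 60 optimizer steps; the
mean Hausdorff distance of about one pixel says the predicted boundaries
deviate from the true ones by roughly a single pixel. The nested classifier
is trained the same way with `fit_if_rcnet()`, and `run_ablation()`
reproduces the four-configuration coupling study (baseline / +mixed input /
+feature fusion / +both) on identical folds and seeds.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/ifrcnet.R synth --n-per-class 20 --image-size 64 --seed 1 --out data/
Rscript inst/cli/ifrcnet.R train-seg --data data/ --out run/ --base-width 16 --epochs 10 --seed 1
Rscript inst/cli/ifrcnet.R ablation --data data/ --out ablation/ --seed 1
```

Every run is fully determined by its arguments and `--seed`; repeated runs
emit byte-identical reports.

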