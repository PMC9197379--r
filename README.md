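# scseVNet

3D brain-tumor segmentation on multi-modal MRI with a V-Net encoder–decoder
augmented by concurrent spatial/channel squeeze-and-excitation (scSE) gating
and a non-local self-attention bottleneck — implemented, trained and
evaluated entirely in R.

The package is aimed at medical-image-analysis practitioners who want a
fully inspectable, dependency-light reference implementation of this
architecture family: every layer's forward *and* backward pass is written
out explicitly (im2col convolutions, transposed-convolution adjoints,
attention, soft Dice gradients) and validated against brute-force oracles
and finite differences, rather than hidden inside a deep-learning
framework.

## The method

A case is four co-registered, skull-stripped modalities (FLAIR, T1, T1ce,
T2; BraTS layout, 240 × 240 × 155 voxels at 1 mm) with labels
{0, 1, 2, 4}, evaluated on three nested regions: whole tumor (WT = {1,2,4}),
tumor core (TC = {1,4}), enhancing tumor (ET = {4}).

* **Preprocessing** — per-modality Z-score with the population standard
  deviation, σ = √(1/N Σ(xᵢ − μ)²); patches of 64 × 128 × 128 × 4 on a
  deterministic grid with strides (15, 25, 25) plus clamped tail origins so
  every voxel is covered (288 patches per case).
* **Network** — five residual encoder stages (filters 20…320, 3×3×3
  kernels, ReLU), stride-2 convolutions for downsampling (no pooling),
  scSE in every stage:
  channel gate `sigmoid(W₂ relu(W₁ · GAP(X)))`, spatial gate
  `sigmoid(Wₛ ∗ X)`, output `X̂ + X̃`; a non-local block at the bottleneck:
  `y = softmax(θ(X) φ(X)ᵀ) g(X)`, `z = yW + b` with θ, φ, g projecting to
  C/2 channels; four decoder stages with transposed convolutions and
  additive skip fusion; 1×1×1 softmax head over 4 classes.
* **Training** — soft Dice loss
  `1 − meanₖ (2Σpₖgₖ + ε)/(Σpₖ + Σgₖ + ε)`, hand-derived gradients, Adam,
  foreground-biased patch sampling, seeded and resumable checkpoints.
* **Evaluation** — Dice, sensitivity, specificity and HD95 (95th-percentile
  pooled symmetric surface distance via an anisotropic Euclidean distance
  transform) per region, with undefined (empty-region) cases flagged rather
  than scored.
* **Synthetic phantoms** — seeded BraTS-shaped cases with nested
  ellipsoidal tumor regions and per-modality contrast, so the entire
  train/predict/evaluate pipeline runs with no external data.

## Worked example

Generate a desk-scale phantom, overfit the tiny network preset on it, and
evaluate the prediction against the ground truth:

```r
library(scseVNet)

phantom <- generatePhantom(tinyPhantomSpec(seed = 1))
phantom
#> MultiModalVolume 'tiny-phantom': 32 x 32 x 24 voxels, spacing 1x1x1 mm
#>   labels: 0=22479 1=534 2=1474 4=89

cfg <- tinyNetworkConfig(seed = 42)
run <- trainModel(list(phantom), cfg, steps = 300, lr = 1e-3, seed = 7)
round(run$log$loss[c(1, 100, 200, 300)], 3)
#> [1] 0.937 0.399 0.081 0.051

pred <- predictCase(run$model, phantom)
evaluatePair(pred, labelVolume(phantom), caseId = caseId(phantom))
#>        case_id region      dice sensitivity specificity hd95
#> 1 tiny-phantom     ET 0.9943503   0.9887640   1.0000000    0
#> 2 tiny-phantom     WT 0.9685039   0.9971388   0.9942168    1
#> 3 tiny-phantom     TC 0.9726349   0.9983949   0.9985806    1
```

The loss falls from 0.94 to 0.05 over 300 steps (about 90 s on one CPU) and
the overfit model segments its own phantom with Dice > 0.96 in all three
regions — the expected behaviour for a correctly wired, trainable network
at desk scale.  The full published architecture is available as
`defaultNetworkConfig()`; its symbolic layer shapes:

```r
head(shapeTrace(defaultNetworkConfig()))
#>   layer       path  D   W   H   C
#> 1     0       stem 64 128 128   4
#> 2     1    encoder 64 128 128  20
#> 3     2    encoder 32  64  64  40
#> 4     3    encoder 16  32  32  80
#> 5     4    encoder  8  16  16 160
#> 6     5 bottleneck  4   8   8 320
```

Real BraTS cases (NIfTI directories with `_flair/_t1/_t1ce/_t2/_seg`
suffixes) load with `loadCase()` and run through the same
`trainModel()` / `predictCase()` / `evaluateCases()` pipeline.  A thin
command-line wrapper with `generate`, `train`, `predict` and `evaluate`
subcommands ships in `inst/cli/scsevnet.R`.

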