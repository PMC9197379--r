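---
title: "Methods: a squeeze-and-excitation, non-local V-Net for 3D brain-tumor segmentation"
author: "scseVNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a squeeze-and-excitation, non-local V-Net for 3D brain-tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scseVNet)
```

## The problem and the model

Gliomas are segmented on multi-parametric MRI into three nested evaluation
regions: whole tumor (WT, everything abnormal), tumor core (TC, everything
except the peritumoral edema), and enhancing tumor (ET).  In the BraTS data
layout a case is four co-registered, skull-stripped, 1 mm isotropic volumes
of 240 x 240 x 155 voxels — FLAIR, T1, T1ce and T2 — plus an expert label
map over the raw labels {0, 1, 2, 4}.

`scseVNet` implements a V-Net-style volumetric encoder–decoder for this
task, with two attention mechanisms inserted into every stage:

* **scSE** (concurrent spatial and channel squeeze-and-excitation): the cSE
  branch global-average-pools the feature map to one value per channel,
  passes the squeezed vector through a C → C/r → C fully connected
  bottleneck (ReLU then sigmoid) and rescales each channel by its gate; the
  sSE branch collapses the channels with a 1x1x1 convolution to a sigmoid
  spatial gate that rescales each position.  The block output is the sum of
  the two branches.  With zero-initialized weights both gates are 0.5 and
  the block is exactly the identity, which keeps residual stages
  well-behaved at initialization.
* A **non-local self-attention block** at the bottleneck: 1x1x1 projections
  theta, phi and g map the C-channel feature map to C/2 channels; the
  attention matrix is the row-softmax of theta phi^T over all N = D·W·H
  spatial positions (normalized over the enumerated position, so each row is
  a probability distribution); the attended features A·g are projected back
  to C channels.  Because all projections are 1x1x1 and attention depends
  only on content, the block is equivariant under spatial permutations — a
  property the test suite checks directly.

The encoder has five stages at successively halved resolution (filters 20,
40, 80, 160, 320 by default).  Each stage applies one (stage 1) or two 3x3x3
convolutions with ReLU, scSE gating, and a residual addition of the stage
input; downsampling is a stride-2 3x3x3 convolution that doubles the
channels — there is no pooling operator anywhere.  The decoder has four
stages: a stride-2 transposed convolution (kernel 3x3x3, mirroring the
downsampling convs) halves the channels and doubles the resolution, the
mirror encoder stage is fused in, and convolutions + scSE + residual follow.
A 1x1x1 convolution to four channels and a voxelwise softmax produce the
class probabilities.  `shapeTrace(defaultNetworkConfig())` reproduces the
ten layer input shapes of this architecture exactly.

## Design choices where the design was open

Several details of the published architecture description are ambiguous or
internally inconsistent; the package fixes them as follows, with the
alternative kept available where it is cheap.

* **Excitation order.**  The excitation formula as printed reads
  ReLU(W2 · sigmoid(W1 s)), while the surrounding description says the first
  layer uses ReLU and the second sigmoid.  Multiplicative gating needs an
  output in (0, 1), so the package defaults to the standard SE order
  (sigmoid last); `cseExcite(..., order = "literal")` evaluates the printed
  order for auditability.
* **Skip fusion.**  Additive fusion is the default: the architecture
  table lists the first decoder stage's input as 8 x 16 x 16 x 160, which
  matches deconv(320 → 160) plus a 160-channel skip added elementwise;
  concatenation would give 320 channels.  `skipFusion = "concat"` is still
  available (the shape trace then reports the doubled channel counts, and
  the residual identity inside a concat stage is the upsampled tensor, since
  the fused tensor's width no longer matches the stage output).
* **scSE placement.**  Unstated in the source description; the package
  places it after the stage's convolutions and before the residual addition,
  which preserves the zero-initialization identity property above.
* **Non-local residual.**  The output projection formula has no residual
  term, unlike the canonical non-local block; the default follows the
  formula literally (`residual = FALSE`), with the canonical variant behind
  the flag.
* **Label semantics.**  The data description glosses label 1 as TC, 2 as ET
  and 4 as WT, which conflicts with the standard BraTS composition
  (WT = {1,2,4}, TC = {1,4}, ET = {4}).  The standard composition is the
  default — it makes the regions nested, as the evaluation protocol assumes
  — and `regionMasks(..., mode = "literal_paper")` preserves the literal
  reading.  Which one the original authors actually evaluated cannot be
  determined from the text.
* **Final stage.**  The table's last row (filter count 4) conflicts with the
  textual description of a 1x1x1 convolution to four categories after the
  last decoder stage; the package follows the text: stage-9 convolutions at
  20 channels, then the 1x1x1 softmax head.

## Preprocessing and patching

Each modality is standardized independently by Z-score with the
**population** (1/N) standard deviation.  Whether the statistics should be
computed over the whole volume or only over nonzero (brain) voxels is not
specified in the source description; the default is `whole_volume` (the
literal formula), and `nonzero_only` is offered because skull-stripped
backgrounds are zero-heavy and compress the dynamic range of the brain
voxels.  Constant volumes are rejected (`DegenerateInputError`) rather than
silently divided by zero.

Model inputs are 64 x 128 x 128 x 4 patches (depth, width, height, channel;
depth is the NIfTI third axis) cut on a deterministic grid with strides
(15, 25, 25).  Those strides alone leave the last 12 columns/rows and top
slices of a 240 x 240 x 155 volume uncovered, so a clamped tail origin
L − P is appended per axis; inference must predict every voxel.  For the
BraTS shape this yields 8 x 6 x 6 = 288 origins.  A stride larger than the
patch would leave interior holes no tail rule can repair, so it is rejected
as a configuration error.  At inference, overlapping per-class probability
patches are averaged per voxel and renormalized; the mean (rather than max
or last-wins) keeps stitched probabilities smooth across patch seams, and
stitching the one-hot encoding of a label map reproduces it exactly.

## Loss, optimization and training

Training minimizes a soft Dice loss: one minus the mean over the four
classes of (2 Σ p g + ε) / (Σ p + Σ g + ε) with ε = 1e-5, background
included by default (configurable).  The gradients of the whole network —
convolutions via im2col, transposed convolutions as the adjoint maps, scSE,
softmax attention, and the loss — are hand-derived; the test suite verifies
every parameter tensor against central finite differences, and a dedicated
oracle test checks the vectorized attention against a per-position O(N^2)
loop.  The optimizer is Adam (default learning rate 1e-4; the tiny preset
uses 1e-3, which is documented as a config value, not a claim about the
original training run — batch size, optimizer and schedule of that run were
never published).  Patches are sampled with a foreground bias of 0.5:
half the draws come from patches containing tumor voxels, since tumor is
rare.  Weight initialization is a seedable fan-in truncated normal with
zero biases, so runs are bit-reproducible given the seed.

## Evaluation

Four indexes per region: Dice, sensitivity, specificity, and HD95 — the
95th percentile of the pooled symmetric surface-to-surface distances, with
surfaces defined by 6-connectivity face-neighbours (volume boundary counts
as background) and distances computed by a separable anisotropic Euclidean
distance transform in physical units.  The percentile mechanics of the
original evaluation are not published; the pooled-symmetric convention used
here is the common BraTS one, and it is validated against an all-pairs
brute-force oracle.  When a region is empty in both masks (many cases have
no ET or TC), the metric is **undefined** and reported as `NA` and counted
separately — not imputed as 0 or 1 — making the pathology explicit instead
of silently dragging down averages.

## The synthetic phantoms

`generatePhantom()` builds a brain ellipsoid containing three nested tumor
ellipsoids — edema (label 2), core (label 1), enhancing centre (label 4) —
so the standard region composition is nested by construction.  Each
modality is its class-mean intensity (a stylized contrast table: FLAIR/T2
bright in edema, T1ce bright in enhancing tumor, T1 hypointense in tumor)
plus independent Gaussian noise of sd 5 on a ~100 intensity scale; voxels
outside the brain are exactly zero, emulating skull-stripping.  The
phantoms deliberately model geometry, multi-channel contrast and noise —
not MRI physics: no bias fields, no Rician noise, no partial-volume
effects, no realistic tumor morphology, and single-focal tumors only.
Passing tests therefore demonstrate that the implementation is correct and
trainable, not that the architecture reaches any particular accuracy on
real BraTS cases; the published validation-set Dice figures require the
accession-gated dataset and a 420,000-step GPU training run, which is out
of scope here.

## Problem sizes and numerical notes

The test suite and the acceptance script run everything at desk scale, a
deliberate choice so the whole package verifies on one CPU in minutes: the
tiny phantom preset is 32 x 32 x 24 voxels with 16^3 patches and a
8/16/32/64/128-filter network (about 2.1 M parameters), overfit for 300
steps; oracle checks use feature maps with at most 64 spatial positions;
the patch-coverage and stitching checks do run at the full 240 x 240 x 155
BraTS shape, where they are pure array plumbing.  Ties in the stitched
argmax resolve to the first (lowest) class index.  Softmax rows are
max-shifted before exponentiation.  The Adam state and parameters are plain
R arrays; checkpoints store them with the architecture fingerprint (a JSON
digest of the configuration), and both resuming and loading refuse a
fingerprint mismatch.
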