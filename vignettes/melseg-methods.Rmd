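---
title: "Melasma segmentation with HHBSNet: model, data and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melasma segmentation with HHBSNet: model, data and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Melasma presents as symmetric brown facial patches whose defining visual
properties — low contrast against surrounding skin, blurred irregular
borders, sensitivity to lighting and specular reflection — make per-pixel
segmentation genuinely difficult. `melseg` implements HHBSNet, a lightweight
encoder network for six-class facial segmentation (background, forehead,
melasma lesion, chin, left/right face), with two attention blocks at its
core.

**GCSA** applies, in order: (1) *channel attention*, a two-layer MLP
(`C -> C/4`, ReLU, `C/4 -> C`, sigmoid) acting along the channel axis
independently at every spatial position — deliberately *without* any global
pooling, so the gate can vary per pixel; (2) a *4-group channel shuffle*,
the reshape–transpose–flatten permutation that lets subsequent convolutions
mix information across groups; (3) *spatial attention*, a
`7x7 conv -> BN -> ReLU -> 7x7 conv -> BN -> sigmoid` pipeline whose gate
multiplies the shuffled map (the block's immediate input, not the original
pre-shuffle features).

**MCF** runs five parallel branches — 1x1 conv; depthwise-separable 3x3
convolutions at dilation rates 6, 12 and 18 ("same" padding equal to the
rate, so resolution is never lost); and a global-average-pooling branch
broadcast back over space — concatenates them to `5C` channels, projects to
`C`, calibrates the merged map with a channel gate (pooled two-layer MLP)
and a spatial gate (per-pixel channel mean/max through a 1x1 conv), and
fuses `F_c' + F_s' + F` through a final 1x1 conv.

The trunk is: backbone → infusion (first + last backbone levels) → GCSA →
MCF → global feature fusion → 1x1 classifier → bilinear upsampling to input
resolution → softmax. The objective is the hybrid
`L = lambda*L_CE + (1-lambda)*L_FL` with focal loss
`alpha*(1-p_t)^gamma * (-log p_t)`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.5 | cross-entropy vs focal mixing weight |
| `alpha`, `gamma` | 0.25, 2 | focal balance and focusing strength (standard settings; the source recipe leaves them open) |
| dilation rates | 6, 12, 18 | receptive-field ladder of the MCF branches |
| shuffle groups | 4 | channel shuffle group count |
| bottleneck ratio | 4 | `C -> C/4` reduction in both attention MLPs and the 7x7 conv pair |
| `working_width` | 256 (`mobile`), 32 (`tiny`) | trunk channel count after infusion |
| `lr`, momentum, batch | 7e-3, 0.9, 8 | reference SGD recipe (180 epochs, step decay) |

## Design decisions where the architecture description is open

Several structural details are not fixed by the published block equations;
the package resolves them as follows, and records each choice here rather
than in scattered comments.

* **Channel attention has no pooling.** The channel MLP acts per spatial
  position (the permutation moves channels to the last axis); inserting
  SE-style global pooling would change the block into something else.
* **Spatial attention multiplies the shuffled map**, reading the gate
  equation literally.
* **Calibration operates on the projected C-channel map**, not the 5C
  concatenation — the only reading that keeps the gate shapes consistent
  with the block's declared `H x W x C` output.
* **The residual term in MCF fusion** (`+ F` before the output projection)
  follows the surrounding prose of the block description; it is exposed as
  `mcf_residual` in `network_config()` so the pure equation form can be
  recovered.
* **Block order** backbone → infusion → GCSA → MCF → global fusion → head,
  with one GCSA and one MCF instance, is adopted as the package's assembly;
  the original figure does not pin the sequence.
* **7x7 convolutions** use zero padding 3, stride 1; MLPs carry biases; BN
  appears only where the equations place it (the spatial submodule, the MCF
  branch outputs).
* **Backbones.** An inverted-residual ("mobile", strides 4/8/16/32)
  backbone is provided for realistic use, and a small 4-stage conv-BN-ReLU
  backbone ("tiny", strides 2/4/8/16) for tests and CPU-scale studies. Both
  are randomly initialized; no pretrained weights are required anywhere.
* **Ties in the argmax mask** break toward the lower class index;
  coordinates are pixel-centered with origin at the top-left.

## The numerical engine

No deep-learning framework exists for R in this package's dependency
envelope, so the tensor engine is part of the package: im2col gathers plus
BLAS matrix products for convolutions (with a pointwise fast path for 1x1
kernels and a flipped-kernel convolution for stride-1 input gradients),
hand-derived analytic backward passes for every layer, and pixel-center
bilinear interpolation whose adjoint is used in backpropagation. The entire
composition is validated against central finite differences in the test
suite's development history and against naive nested-loop convolution
oracles in the shipped tests.

Numerical choices: probabilities are clipped at `1e-7` before logarithms in
the probability-facing loss functions; the training path computes loss and
gradient directly from logits via log-sum-exp, which stays exact even where
the softmax saturates. Batch-normalization uses running statistics in
inference and the statistics of the current map in training; because images
pass through the network one at a time, training-mode statistics are
per-image (gradients are still averaged over the batch). This is a
deliberate simplification; its visible consequence is a small lag between
training-mode and inference-mode metrics early in training.

## The synthetic scene generator

Clinical melasma photographs are private; the generator stands in for them
and defines the package's study conditions. Each scene is an elliptical
face over a dark background, partitioned into forehead (upper band), chin
(lower band) and left/right cheek regions; melasma lesions are
thresholded-at-half-maximum Gaussian bumps modulated by smoothed noise —
irregular, ragged-bordered patches with radius 5–11 % of the image side,
matching the patch-scale (not freckle-scale) morphology of melasma. Lesions
are recolored by a mean intensity offset of 0.12 with a brown channel
weighting, their image-space alpha is blurred (sigma 1.5 px) to soften
borders while the mask keeps the sharp support, and the image then receives
an illumination gradient (up to 15 %), specular highlights and additive
Gaussian noise (sd 0.02). All values are on the [0, 1] intensity scale and
were chosen once as clinically plausible defaults.

What passing tests on these scenes shows: the architecture can represent
and learn the map from face-like low-contrast imagery to the six-class
layout, the losses/metrics/statistics behave exactly as specified, and the
training loop optimizes. What it does not show: performance on real VISIA
photographs, robustness to pose/occlusion, or clinical-grade boundary
accuracy — real faces have texture, hair and anatomy the generator does not
attempt.

## Desk-scale study sizes

The shipped experiments use the tiny backbone at 64x64 with 8 training
scenes and up to 500 full-batch SGD steps (learning rate 0.02, halved every
200 steps, no augmentation, fixed seed) — sizes chosen so the whole study
runs comfortably on a single CPU. Under these conditions the network
reaches a training mean IoU of 0.9 in well under the step budget; the
acceptance script additionally evaluates four held-out scenes to report
generalization-side metrics. The 180-epoch, 512x512, batch-8 reference
recipe remains available through `train_config()` defaults for users with
real data and more compute.

## Known limitations

* Single-image BN statistics (above) — a batched engine would remove the
  train/eval lag.
* The evaluation AUC pools all pixels of a collection; per-image ROC curves
  are not drawn.
* The generator's "Dice" reporting convention is per-image lesion-class
  Dice averaged over images, which is intentionally *not* the same quantity
  as global-counts F1 (the two coincide only when computed from the same
  pooled counts; the package tests assert that identity separately).
* Pure-R training is practical at desk scale only; 512x512 training is
  possible but slow.
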