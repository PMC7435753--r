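---
title: "Cascaded nodule detection: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded nodule detection: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulecascade)
```

## The detection problem

Pulmonary nodules are small, roughly circular lesions that appear bright
on chest CT. Detecting them automatically is hard for a single
classifier because the image is full of look-alikes: vessel
cross-sections inside the lung share the nodules' intensity, and ribs or
sternum fragments outside the lung share their size and shape. This
package implements a coarse-to-fine cascade of three convolutional
sub-networks, each eliminating one family of confounders:

1. **Parenchyma segmentation** — a U-Net-like network whose first layer
   is an inception block (parallel 1x1 and factorized 1x3/3x1 branches)
   and whose skip connections are *dense*: each layer receives every
   earlier feature map, resampled by the power-of-two ratio between
   resolutions. Its output masks away everything outside the lung
   fields, so outside-lung distractors can never reach the later stages.
2. **Candidate detection** — a U-Net-like network in which every
   convolution stage is a dilated-convolution block (channel-preserving
   inception followed by a 3x3 convolution with dilation rate 2). The
   dilation enlarges the receptive field from `k` to
   `k + (k-1)(d-1)` without pooling away resolution, which matters for
   lesions a few pixels across. This stage is deliberately
   over-inclusive: vessels count as candidates here.
3. **Nodule determination** — a network built from multi-resolution
   convolution blocks (three parallel routes at full, half-row and
   half-column resolution, recombined by axis-wise transposed
   convolutions; channels triple) and multi-scale pooling blocks (2x2,
   3x3, 4x4 and 5x5 stride-2 convolutions in parallel, each projected to
   a quarter of the channels, so channels are conserved while the grid
   halves). It separates true nodules from vessel-like candidates by
   shape.

Each stage's probability map gates the next stage's input: stage 2 sees
the image multiplied by the parenchyma map, stage 3 sees the
candidate-gated image stacked with the candidate probability map
(2-channel input by default). At inference the gates are hard
thresholdings (default 0.5). During training the gates start *soft* —
plain products with the probability maps, so one loss on the final
nodule map differentiates through all three sub-networks — and switch
halfway through (`hard_gate_from`, default 0.5) to *straight-through*
hard gates: the forward pass thresholds exactly as inference will, the
backward pass treats the threshold as the identity. Training purely
with soft gates turned out to leave the stage probabilities
uncalibrated against the hard threshold — a stage can learn to signal
candidates at, say, 0.15, which works under soft products but is
annihilated by hard gating — so the annealed schedule trains the late
epochs in exactly the regime the cascade is evaluated in, while keeping
the single end-to-end loss differentiable throughout.

## The joint loss

Training minimizes

$$L_j = \mu_1 L_{pix} + \mu_2 L_{perc} + \mu_3 L_d,$$

with defaults $\mu = (0.9, 0.9, 0.999)$.

* $L_{pix}$ is the mean squared error between the predicted nodule map
  and the binary ground truth, normalized by the pixel count.
* $L_{perc}$ is a perceptual distance: both maps pass through a fixed
  VGG-19-style convolutional stack and the squared feature distance at
  the 12th convolution, normalized by that layer's spatial size, is
  taken. The extractor's weights are drawn once from a seeded
  He-normal initialization and never trained; with fixed weights the
  loss is a valid, reproducible metric on feature space and requires no
  external download. Pretrained weights could be substituted by loading
  a different extractor object, but are deliberately not a dependency.
  Grayscale inputs are replicated to three channels. Whether "layer 12"
  counts only convolutions or pooling layers too is genuinely ambiguous;
  convolution-only counting is the default and the alternative is a
  constructor option.
* $L_d$ is a modified dice loss. For non-empty ground truth it is the
  *soft* dice $1 - 2\sum pg / (\sum p + \sum g)$ — differentiable, and
  exactly the set-count dice on binary inputs. For an all-zero ground
  truth (a negative sample) the dice is undefined, so the loss becomes
  the L1 magnitude of the prediction, normalized by the pixel count so
  its scale stays commensurate with the dice branch. The normalization
  is this package's choice; an un-normalized L1 would make one negative
  sample outweigh hundreds of positives.

The loss is applied to the final nodule map only, by default. Optional
per-stage auxiliary terms (dice plus pixel MSE of stage 1 against the
parenchyma mask and stage 2 against the candidate mask) can be enabled
with `aux_loss_weight > 0` in `train_cascade()`; they considerably
shorten desk-scale training because the early stages receive direct
supervision instead of waiting for gradients to filter back through two
gates. The focal loss sometimes mentioned alongside these components is
not part of the defined objective and is not implemented.

## Training

All three sub-networks are updated by a single Adam optimizer — no
parameter is excluded, and gradients cross the soft gates — matching the
end-to-end strategy rather than alternating per-stage optimization. The
reference hyperparameters are learning rate 0.001, batch size 40, 100
epochs, and weight decay 1e-4; the "regularization coefficient" is
interpreted as an L2 weight-decay coefficient of 1e-4, since a penalty
weight of 1e+4 would dominate the loss by orders of magnitude. The
optimizer is not named in the reference description; Adam with its
standard moment coefficients (0.9, 0.999) is used. Everything is seeded:
weight initialization, the train/validation split, batch order, and the
phantom generator, so a fixed configuration reproduces its loss
trajectory bit-for-bit on CPU.

## Implementation notes

No deep-learning framework is used: the package implements its own
reverse-mode differentiation tape in R, with convolution, transposed
convolution, pooling and resampling kernels in C++ (im2col plus BLAS
matrix products via RcppArmadillo). Every kernel's gradient is checked
against central-difference numerics in the test suite. Design choices a
maintainer should know:

* **Output-size convention.** The spatial size of a dilated convolution
  is `o = floor((i + 2p - n) / s) + 1` with `n = k + (k-1)(d-1)` — the
  standard sign convention for padding, under which "same" padding
  `p = (k-1)d/2` preserves size at stride 1.
* **Inception topology.** The block uses three branches (1x1 bottleneck;
  bottleneck + one 1x3/3x1 pair; bottleneck + two stacked pairs) and a
  trailing 1x1 projection; no pooling branch. The candidate-stage
  variant uses half-width branches and projects back to the input width,
  so it is channel-preserving.
* **Resolution bookkeeping.** The reference parameter tables list four
  stride-2 de-convolutions against three stride-2 encoder convolutions,
  which cannot close over resolution; the decoder here has three
  upsampling stages plus one full-resolution refinement stage.
* **Multi-scale pooling padding.** Per-branch padding
  `floor((k-1)/2)` makes all four branch outputs `ceil(i/2)`, so they
  concatenate; all four branches use stride 2. The 4x4/2x2 even kernels
  shift features by half a pixel, which is immaterial after the 1x1
  projections.
* **Dense resampling operators.** Down: block-average pooling; up:
  nearest-neighbour — parameter-free and order-preserving.
* **Normalization and activation.** Batch normalization and ReLU follow
  every convolution (sigmoid heads excepted); both are configurable.
  Batch statistics are used during training and running averages
  (momentum 0.1) at inference.
* **Head initialization.** Output-head biases start at -2 so the
  sigmoid begins near 0.12; for sparse targets this removes the long
  initial phase of un-learning a half-gray prediction.
* **Gradient clipping.** Gradients are rescaled when their global norm
  exceeds 100 (`grad_clip` in `train_cascade()`); Adam is invariant to
  uniform gradient scale, so this only damps occasional spikes.
* **Stage-3 input.** A full probability map (not candidate crops) enters
  stage 3, stacked with the gated image; this preserves intensity
  context around each candidate.

## The phantom generator

Real CT with expert annotations cannot ship with a package, so the
generator builds 2D chest phantoms that reproduce the *decision
structure* of the problem: a bright thorax ellipse (intensity 0.55) on a
dark background, two dark elliptical lung fields (0.2), bright circular
nodules (0.75, diameters 5-11 px by default) strictly inside the lungs,
thin bright vessel curves at the *same* intensity as nodules (radius
about 1 px, length 8-18 px) so that only shape separates the two, bright
distractor blobs (0.85) outside the lungs but inside the thorax, and
additive Gaussian noise (sigma 0.03), clipped to [0, 1]. Ground truth is
nested exactly as the cascade expects: nodule mask within candidate mask
(nodules plus vessels) within parenchyma mask. About 30% of generated
samples are negative (no nodules) by default — the fraction is a
parameter since no canonical value exists — which exercises the
negative-sample branch of the dice loss.

What the phantoms do **not** model: CT texture, scanner physics, partial
volume effects, 3D anatomy, juxta-pleural nodules, or intensity overlap
between nodules and parenchyma. A cascade that passes the phantom study
has demonstrated that the architecture, losses, gating and training
machinery work end-to-end — not that it matches clinical performance on
real scans, which requires the real datasets and full-scale training.

## Evaluation

Accuracy, sensitivity and specificity are the usual ratios of
TP/FP/TN/FN; a zero denominator yields `NA` rather than a silent 0.
Because no canonical "sample" population is defined for these ratios,
both levels are reported: pixel-level (every pixel a sample) and
lesion-level, the headline, where 8-connected components of the
binarized nodule map are matched greedily (nearest first) to annotation
centers, a hit being a component centroid within `diameter/2` of the
center (an IoU criterion is available). Components smaller than 7
pixels are discarded before matching: a pulmonary nodule is by
definition at least 3 px across, and no disc of that diameter covers
fewer than 7 pixels, so smaller components are noise specks, not
candidate lesions (`min_area` in `match_lesions()`). The precision-recall curve
sweeps the binarization threshold, aggregates lesion counts over the
dataset, and integrates precision over recall by the trapezoid rule,
anchored at recall 0 with the most conservative threshold's precision;
precision with no detections is taken as 1. Lesion-level recall is
monotone in the threshold for detectors whose components do not merge;
heavy sub-threshold noise can break monotonicity by fusing components —
a property of lesion-level scoring itself, not of the implementation.

## Desk-scale study sizes

The scaled-down end-to-end study run by `scripts/acceptance.R` and the
acceptance tests uses 200 phantoms of 64 x 64 pixels (150 training, 50
held out), the smallest cascade configuration (`width_scale = 1/16`,
i.e. stem width 4, encoder widths 8/16/32), a width-1/8 perceptual
extractor, batch size 4 and 20 epochs with auxiliary stage supervision
(`aux_loss_weight = 10`, sized so the direct per-stage gradients are
commensurate with the joint-loss gradients arriving through the gates).
These sizes were chosen once so that a full study trains in
minutes on one CPU core while leaving every architectural element of the
full-width model exercised; the full-width configuration
(`width_scale = 1`) is the package default everywhere else.

## Known limitations

* 2D slices only, matching the pair-wise slice processing of the
  method; no 3D context.
* The perceptual extractor's random weights make $L_{perc}$ a generic
  feature-space metric rather than a semantically pretrained one.
* Batch normalization with very small batches is noisy; the desk-scale
  configuration compensates with more steps.
* The CLI's `predict` writes 16-bit PNG maps only; volumetric export is
  limited to what `write_slice()` offers.
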