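---
title: "Dual-stream boundary-aware nuclei segmentation: models, parameters and design choices"
author: "nucleifuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream boundary-aware nuclei segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the segmentation model and its assumptions, the parameters
that matter, what the synthetic data generator does and does not
emulate, the numerical conventions, and the places where the design was
genuinely open and a choice had to be made.

## The problem

Nuclei in H&E-stained tissue are densely packed, overlapping, and
variably stained; segmentation models that optimize region overlap
alone tend to produce over-smoothed contours exactly where pathology
pipelines need precision (morphometry, counting, grading). The model
here attacks that trade-off in three places at once: an encoder that
*separates* contextual from edge-sensitive features, a fusion module
that reweights them spatially before decoding, and a loss term that
penalizes disagreement between the *gradients* of the predicted and
true masks rather than their values.

## Architecture

**Encoder.** Two streams process the input concurrently and downsample
stride-2 per level, so their feature maps stay resolution-synchronized
(the fusion stage asserts this at every level). The global stream's
per-level block is `conv 3x3 (stride 2) -> batch-norm -> deformable
conv 3x3 (dilation d_l) -> GELU`, plus a residual 1x1 stride-2
projection of the level input; dilation and deformable sampling grow
the receptive field in place of extra pooling. The literal operation
order (batch-norm *before* the deformable convolution) is kept even
though normalizing before a sampling layer is unusual. The local stream
consumes the image stacked with its Sobel gradient magnitude and uses
plain `conv 3x3 (stride 2) -> batch-norm -> GELU` blocks; strided
convolutions replace pooling throughout. Both streams start with one
full-resolution conv-BN-GELU stem.

The deformable convolution is the classic learned-offset variant: a
zero-initialized 3x3 convolution predicts two offsets per kernel tap
and per position, and taps sample the input bilinearly at the displaced
locations. At zero offsets it reduces *exactly* to a dilated
convolution (an equivalence the test suite asserts), which also makes
the `use_deformable = FALSE` fallback a faithful ablation.

**Fusion.** Each level's two maps are projected by 1x1 convolutions to
a common width `C`, concatenated (width `2C`), and summarized across
channels by average and max maps; a shared 7x7 convolution plus sigmoid
turns the two summaries into a spatial attention map that reweights the
concatenated features. "Shared" is read as one attention convolution
shared *across pyramid levels* (the CBAM convention); the alternative —
one per level — would only add parameters without changing any
contract. Attended maps from all `L` levels are resampled bilinearly to
a common base resolution and concatenated into a `2CL`-channel
hypercolumn, which a depthwise-separable 3x3 -> batch-norm -> GELU
block compresses to `D'` channels.

*Where does the hypercolumn live?* The decoder contract fixes this: each
decoder runs `L` transposed 2x2 (stride-2) stages and must emit a map at
the input resolution, and its stage-`j` skip connection must be
conformable. With encoder levels at `input / 2^l`, the only resolution
at which the fused map can seed such a decoder is the *coarsest* level,
`input / 2^L`. The fusion function therefore defaults its base size to
the coarsest level (callers can pass any size; resampling is bilinear in
either direction), and fine detail re-enters through the skip
connections rather than through the hypercolumn itself.

**Decoders.** The region decoder's stage `j` upsamples, applies
batch-norm and GELU, then concatenates a 1x1-projected skip: the
channel-concatenation of both streams' maps at the matching resolution
(the stems at full resolution for the final stage). The boundary
decoder is built identically but takes its skips from the local stream
only, the stream that carries edge information. Each head is a 1x1
convolution; sigmoids are applied in `forward()`. At inference the
boundary map refines the region map,
`Y_R = clamp(Y_seg * (1 + lambda * Y_edge), 0, 1)`; the product can
exceed 1, and clamping preserves the probability reading used by the
0.5 decision threshold. Training supervises `Y_seg` and `Y_edge`
directly (refinement is an inference-time step); a config switch
(`supervise_refined`) lets the refined map be supervised instead, for
experimentation.

## The objective

`L = alpha * L_seg + beta * L_edge + gamma * L_glga`, defaults
0.6/0.2/0.2.

* `L_seg` is `dice_mix * (1 - softDice) + (1 - dice_mix) * BCE` with
  `softDice = (2*sum(p*y) + eps) / (sum(p) + sum(y) + eps)`. The
  Dice:BCE ratio inside the hybrid is not pinned anywhere authoritative;
  `dice_mix = 0.5` treats them symmetrically. `eps = 1` keeps the term
  defined (and equal to zero) on empty masks, which the synthetic
  generator can produce in aggressive augmentation regimes.
* `L_edge` is mean BCE on the boundary head, probabilities clamped to
  `[1e-7, 1 - 1e-7]`.
* `L_glga` applies 3x3 Sobel operators to the predicted and true region
  maps, reduces to gradient magnitudes, and takes the mean absolute
  difference. Replicate padding is used: zero padding would
  manufacture phantom gradient at the image frame and the loss would
  pay for edges that do not exist. The magnitude uses
  `sqrt(x + 1e-12)` so its gradient is finite on flat regions. The term
  is computed on `Y_seg`, not on the refined map. `gamma` outside
  `[0.1, 0.5]` triggers a warning, not an error — zero is a legitimate
  ablation.

All three terms are zero at a perfect binary prediction (up to the BCE
clamp), and the whole objective is checked against central finite
differences at relative error 1e-3 in the tests.

## Training engine

AdamW (beta1 0.9, beta2 0.999, eps 1e-8) with decoupled weight decay
0.01 applied to convolution kernels only — biases and batch-norm
scale/shift are exempt, the standard convention. Learning-rate schedule:
cosine annealing with warm restarts,
`lr(t) = min_lr + (lr_max - min_lr) * (1 + cos(pi t / T_i)) / 2`,
with cycle lengths `T_0, T_0 * m, T_0 * m^2, ...`. The schedule
constants (`T_0 = 20` epochs, `m = 2`, `min_lr = 1e-6` at the default
scale) are engineering choices; nothing pins them. Gradients are
clipped to a global norm of 5.0 before each step; the post-clip norm of
every step is recorded in the run history. Validation Dice at threshold
0.5 (on `Y_seg`; switchable) drives best-checkpoint saving and early
stopping after `patience` epochs without improvement.

Two configurations ship with the package. `train_config()` carries the
GPU-scale regime (lr 1e-4, batch 16, 200 epochs, patience 15, seed 42).
`tiny_train_config()` is the CPU-scale preset actually used by the
package's experiments: lr 1e-3 and batch 8 — the standard operating
point for a ~50k-parameter model with small batches, where 1e-4 is
needlessly conservative — with `T_0 = 10`, `min_lr = 1e-5`, 30-epoch
cap, patience 8.

Reproducibility: weight initialization, batch shuffling and
augmentation each draw from an RNG stream derived by a 32-bit
avalanche mix of `(seed, stream_id)`, and the streams save/restore the
global RNG state around every draw. Identical configs produce
bit-identical runs; this is asserted in the tests. Batch-norm running
statistics are part of a checkpoint, so a reloaded model reproduces its
saved validation Dice exactly. The `bn_momentum` knob (default 0.1)
exists because a "frozen" model is only frozen if the running moments
are too.

## Synthetic study conditions

`scene_spec()` defaults define the conditions every experiment in the
package runs under: 64x64 fields, truncated-Poisson(8) nuclei per field
(zero draws redrawn — an empty image has no Dice denominator), rotated
ellipses with semi-major axes 3-8 px and minor/major ratio 0.45-0.95,
boundaries modulated by a mild second-harmonic lobe (amplitude 2-8%,
keeping every nucleus star-convex and hence connected), a target
fraction 0.3 of nuclei touching another nucleus, foreground/background
contrast 0.35 on a low-frequency textured background (nuclei darker, as
hematoxylin stains them), ±15% per-image multiplicative stain jitter and
Gaussian pixel noise of sd 0.05. Axis and eccentricity ranges are
stand-ins chosen to look like dense breast-carcinoma fields at this
resolution; no published morphometry was available to calibrate them.

Overlap is placed, not hoped for: `round(overlap_fraction * K)` nuclei
are designated to live in touching pairs (an anchor plus an attachment
whose inscribed discs are forced to intersect), the rest are
rejection-sampled apart. The realized fraction tracks the target to
within about ±0.1 — quantization to whole nuclei plus crowding in dense
fields set that floor — and the tests measure it with an independent
geometric-intersection oracle over the stored placement provenance.

Draw order is z-order: later nuclei overwrite earlier labels on
contested pixels, keeping `instance_labels` single-valued; labels left
empty are dropped and the rest renumbered. The optional color mode
mixes two synthetic stain endpoints (dark violet nuclei, pale pink
background) so the Reinhard path has colored input.

What the generator does *not* emulate: chromatin substructure, stain
deconvolution physics, slide artifacts, out-of-focus blur, and the
long-tailed morphology of real tumors. Passing the package's
generalization checks therefore demonstrates that the architecture,
losses, metrics and training engine work as specified — it does not
certify accuracy on real tissue.

## Preprocessing and augmentation

Pipeline order for RGB input: Reinhard LAB standardization ->
grayscale (luminosity weights 0.299/0.587/0.114) -> bicubic resize ->
[0,1] scaling -> zero-mean/unit-variance. Reinhard needs color, so it
comes first; grayscale precedes resizing to cut cost. Applying Reinhard
and then discarding color is redundant for purely grayscale pipelines,
so a `use_reinhard` switch exists; the reference LAB statistics default
to whatever the caller computes from the first training image
(`lab_stats()`), since no canonical reference slide exists. Masks are
resized nearest-neighbor and re-binarized — bicubic on a binary mask
creates non-binary values. Mask cleaning opens with a disk of radius 1
and drops 8-connected components under 10 px. The disk structuring
element contains offsets with `dy^2 + dx^2 <= (r + 0.5)^2`; at r = 1
that is the full 3x3 neighborhood, under which solid rectangles are
opening-stable (the strict `<= r^2` disc is a 4-neighbor cross that
shaves corners off rectangles). Morphology treats pixels outside the
frame as background, which is what makes a full-frame mask produce an
edge band at the image border.

The boundary supervision target is not defined anywhere authoritative;
the package uses the binarized morphological gradient (3x3 square
element applied `thickness` times, default 1) of the cleaned region
mask — standard, and matched in sharpness to what the
gradient-alignment term rewards.

Augmentation composes flips, bounded rotations (±30° default), elastic
deformation (displacement amplitude 20 px smoothed at sigma 4 px — mild
enough to keep nuclear shapes plausible) and contrast modulation; each
triggers independently with its own probability. One coordinate map is
built and applied to image (bilinear) and masks (nearest, re-binarized)
alike, so geometry never diverges within a sample; contrast touches the
image only.

## Metrics

Dice `2TP/(2TP+FP+FN)`, IoU, pixel precision/recall; boundary F1 at
tolerance delta (default 2 px — a tolerance is standard, its value is
not, and 2 px at 64-256 px resolution matches common practice);
symmetric Hausdorff distance as the exact max-min over boundary pixel
sets (not the 95th-percentile variant). Boundaries for metric purposes
are the 4-connectivity inner boundary, keeping each boundary a subset
of its mask. Distances are exact pairwise Euclidean computations, so
the implementation agrees with brute-force oracles to the last bit.
Degenerate cases are explicit and flagged: both masks empty gives
Dice/IoU/BF1 of 1, exactly one empty gives 0, and an empty boundary set
makes the Hausdorff distance report the image diagonal with an
`empty-boundary` flag so aggregations can exclude it.

## Problem sizes used by the package's own checks

The test suite and the acceptance script run, as the package's chosen
experiment sizes: metric-oracle agreement on 200 random 16x16 mask
pairs; a memorization check (8 fields, one optimization step per epoch,
200 steps, train-set Dice >= 0.95); and a generalization check (200
training fields, 50 held-out, 12 epochs of the CPU preset, seed 42,
held-out Dice >= 0.85 with a finite Hausdorff distance on at least 95%
of images). The ablation harness trains `full`, `no_glga` and `no_hfem`
variants under identical seeds and reports their metric table;
directional differences between variants are reported, not asserted —
effect sizes on the synthetic generator need not match those on real
tissue.

## Known limitations

* Instance-level separation (AJI/PQ) is out of scope; outputs are
  binary region/boundary maps.
* The CPU engine processes batches as whole tensors in one thread; it
  is sized for the 64x64 synthetic regime, not for 512x512 slides.
* Bit-reproducibility holds in the default double-precision mode; the
  config exposes no mixed-precision path.
* The attention convolution is shared across levels; per-level
  attention is a one-line variant but was not needed to meet any
  contract.
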