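---
title: "Color-cast simulation and correction for tongue images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-cast simulation and correction for tongue images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Automated tongue diagnosis needs color-faithful photographs: lighting and
capture conditions shift the recorded colors away from the true tongue
appearance, and those shifts (color casts) corrupt any downstream analysis
that reads health state from tongue color. This package implements a complete
desk-scale pipeline for studying that problem: simulating casts on clean
images, removing them with classical white-balance algorithms or a deep
convolutional regression network, measuring the residual error, and comparing
correctors statistically. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic test bed does and
does not demonstrate.

## Cast simulation

Five canonical degradations are modelled on 8-bit RGB images
(`apply_bias()`):

* **Brightness casts.** Every channel value becomes
  `v * contrast ± offset`, with `contrast ∈ [0.8, 1]` and
  `offset ∈ [0, 30]` levels; the sign distinguishes `lower_brightness`
  from `higher_brightness`. The arithmetic is carried out in floating
  point and clamped to `[0, 255]` only once, at 8-bit quantization (the
  pre-clamp maximum is `255 + 30 = 285` at `contrast = 1`), so the
  transform itself performs no intermediate cropping.
* **Channel casts.** `reddish`, `greenish` and `bluish` add a
  non-negative `adjustment` to the R, G or B channel with saturation:
  `v ← min(255, v + adjustment)`. The canonical training severity is
  `adjustment = 50`.

Randomized-severity casts (`sample_random_bias()`) draw `contrast` and
`offset` uniformly from the ranges above and `adjustment` uniformly from
`[10, 50]`. The lower end of 10 was chosen once so that randomized casts
span mild-but-visible shifts up to the canonical severity; the sampling law
for randomized experiments is this package's choice, as only the fixed
training severity is standardized.

Quantization everywhere uses round-half-away-from-zero applied once at the
8-bit boundary; channel rescaling is computed as `x * num / den` rather than
`x * (num / den)` so mathematically exact halves (e.g. `100 · 255 / 200 =
127.5`) survive floating point and round deterministically.

## Classical correctors

* **Gray world** (`gray_world()`): assumes the scene's average color is
  achromatic; each channel is scaled by `K / mean_c` with
  `K = (mean_R + mean_G + mean_B) / 3`. Undefined when a channel mean is
  zero.
* **Perfect reflection** (`perfect_reflection()`): assumes the brightest
  pixel (maximal `R + G + B`; ties broken by first occurrence in
  column-major order, for determinism) is a white reflector, and scales
  each channel so that pixel maps to `(255, 255, 255)`.
* **SDW** (`sdw_correct()`): gray world with block weighting. The image is
  tiled into 16×16 blocks; each block's weight is its within-block
  *spatial* standard deviation (computed per channel and averaged over
  channels), normalized to sum to one, and the channel means entering the
  gray-world scaling are the weighted block means. The per-block formula is
  not standardized anywhere we know of; we use the spatial reading because
  the method's purpose is to suppress large flat single-color regions, and
  a variance pooled across channels would give a flat saturated region a
  *large* weight (its three channel levels differ) — the opposite of the
  intent. A degenerate image in which every block has zero spatial variance
  falls back to plain gray world.
* **Polynomial chart regression** (`fit_polynomial_map()` /
  `apply_polynomial_map()`): a least-squares linear map from a polynomial
  expansion of observed 24-patch chart colors to the reference chart
  colors, applied per pixel. The default expansion is the standard 11-term
  second-order set `{R, G, B, R², G², B², RG, RB, GB, RGB, 1}`; the three
  linear terms are mandatory so the identity lies in the model class.
  Colors are normalized to `[0, 1]` before expansion for conditioning, and
  the fit refuses rank-deficient designs and fewer patches than terms. The
  nominal sRGB values of the standard 24-patch chart are embedded
  (`colorchecker_chart()`); measured charts can be supplied as CSV.

## The deep correction network

The learned corrector is an image-to-image regression CNN assembled from
two symmetric encoder–decoder **U-Blocks** bridged by a constant-resolution
**M-Block**, with channel concatenation between blocks and a
`BN → 1×1 conv (64) → 3×3 conv (3)` output head — 26 convolutional layers
in total, each followed by a ReLU except the final output convolution.

Each U-Block is a two-level encoder–decoder: two 3×3 convolutions, 2×2 max
pooling, two more convolutions, a second pooling (quarter resolution at the
deepest point), then two bilinear ×2 upsampling stages mirrored by
convolution pairs, with same-level feature concatenation at both decoder
levels and an additive residual connection from block input to block
output — 8 convolutions per block. The M-Block stacks 8 convolutions at
constant resolution. The default widths are 32 intermediate filters and 64
output channels for every block.

Conv-layer allocation: the M-Block (8) and the head (2) are fixed by the
architecture's stated counts, leaving 16 for the two U-Blocks; 8 per U-Block
— two convolutions per level × two levels × (encoder + decoder) — is the
only symmetric allocation consistent with the total of 26. The structural
audit (`audit_network()`) counts the instantiated graph's layers and the
builder refuses a configuration whose count disagrees.

Two wiring details are under-determined by the architecture's published
description and are fixed here as follows:

* **Inter-block fusion**: each block's output is concatenated with that
  block's input along channels before entering the next block; the next
  block's first convolution reduces the widened input back.
* **Residual channel adaptation**: the additive residual inside a U-Block
  meets unequal channel counts (3-channel image input; concatenated inputs
  wider than the output). A 1×1 projection would add convolutions and break
  the audit, so the adaptation is parameter-free: zero-padding when the
  block widens, keeping the leading channels when it narrows. At the second
  U-Block the leading channels of its input are the M-Block output, so the
  residual there effectively carries the fused features forward.

The shallow baseline (`build_dccn()`) is a plain 5-convolution network —
input layer, nonlinear transformation layers, linear output layer — with no
pooling and no batch normalization, trained on 40×40 patches, whose three
scalar color-adjustment parameters are broadcast as constant extra input
channels (all-zero is the neutral setting). Its per-layer widths are not
standardized; this package uses 6→32→32→32→32→3.

Inside the networks all activations are `[0, 1]` floats; images are
quantized to 8-bit only at the boundary (`correct_image()`), which also
reflect-pads inputs whose sides are not divisible by 4 (two poolings
require it) and crops afterwards.

All layers (same-padded convolution via im2col + BLAS, max pooling,
bilinear upsampling with half-pixel centres, batch normalization with
momentum 0.1 and ε = 1e-5) carry hand-derived backward passes; the test
suite verifies them against central finite differences to ~1e-9 relative
error, which is the package's guarantee that the optimizer sees exact
gradients.

## Training protocol

`train_model()` optimizes mean squared error with Adam. Full-scale defaults
(`train_config()`): batch size 32, 200 epochs, learning rate 1e-4, L2
weight decay 1e-5 on convolution weights, and a reduce-on-plateau schedule
that halves the learning rate after 15 epochs without a validation-loss
improvement of at least 1e-6 (the plateau tolerance is this package's
choice; only the patience and factor are standardized). The checkpoint with
the lowest validation loss is retained, together with the BN running
statistics as of that epoch. Per-epoch PSNR in the history is derived from
the epoch MSE; on `[0, 1]` tensors this equals the 0–255 convention because
peak and error rescale together.

Datasets are built by cropping 640×640 images into 160×160 patches at
step 80 (49 per image) and splitting 60/30/10. Splitting is **by source
image**, never by patch: overlapping patches from one photograph are
near-duplicates, and letting them straddle splits would leak training
content into the test set. Whether the original protocol split by patch or
by image is not stated; by-image is the honest generalization measurement
and preserves the ratios.

## Evaluation metrics

All metrics live in `quality_report()`:

* **ΔE (CIE76)**: per-pixel Euclidean distance in CIELAB under the
  standard sRGB → XYZ (D65) → LAB transform, summarized over all pixels of
  a pair into mean, quartiles Q1–Q3 (linear interpolation, `stats::quantile`
  type 7) and maximum. The CIE76 variant is deliberate; CIEDE2000 is out of
  scope. Working severity criteria: mean ΔE < 6 — visually the same image;
  6 ≤ ΔE < 15 — mild cast; ≥ 15 — cast. The boundary value 15 is assigned
  to the severer class (conservative flagging).
* **MAE / RMSE** on levels normalized to `[0, 1]` (the scale on which such
  results are conventionally tabulated); **PSNR** in dB against a peak of
  255, reported as `Inf` for identical images rather than erroring;
  the two scales are stated in the report so they cannot be confused.
* **SSIM** with the originating convention: 11×11 Gaussian window
  (σ = 1.5), stabilizers `c1 = (0.01·255)²`, `c2 = (0.03·255)²`, computed
  per channel on 0–255 levels with *valid* window placement, the map
  averaged and then averaged over channels. `SSIM(x, x) = 1` holds exactly
  in floating point because numerator and denominator of each window term
  are computed from identical expressions.

ΔE quartiles are computed at pixel level over one image pair; whether the
original tables aggregated at pixel or patch level is not stated, and the
pixel-level choice is labelled in the outputs.

## Statistical comparison

`bootstrap_evaluate()` draws 40 resamples with replacement at the size of
the per-image metric list and reports the mean and standard deviation of the
resample means. `paired_t_test()` computes the classical paired t statistic
with a two-sided p-value on n−1 degrees of freedom, declaring significance
at p < 0.001; identical vectors are reported as t = 0, p = 1 rather than
erroring. No multiple-testing correction is applied across the 5 scenarios
× 2 metrics — p-values are raw, matching the comparison protocol being
reproduced, and the output documents this.

## The synthetic test bed

`generate_tongue_image()` renders a deterministic-for-seed scene: an
anti-aliased reddish ellipse (base color (180, 90, 95), jittered geometry
drawn from the seed, fully inside the canvas) with a radial lightness
gradient (amplitude 0.3, pushing highlight pixels near saturation so
channel-cast clipping is exercised alongside the linear path), per-pixel
Gaussian speckle (σ = 6 levels), optional pale coating blobs in the upper
tongue half (probability 0.5), on a neutral gray background. Uniform color
blocks (`generate_color_blocks()`) are drawn truncated-Gaussian around the
tongue hue with 20% neutral outliers. Realism is deliberately minimal: the
correction task depends on color statistics, not anatomy, and a fully
specified renderer keeps every test reproducible from a seed.

What passing tests on this bed shows: the formulas are implemented
correctly, the networks learn and remove simulated casts end-to-end, and
the statistical machinery is calibrated. What it does not show: performance
on real tongue photographs, whose texture, specular highlights, mixed
illumination and camera processing the renderer does not model. Published
full-scale results on real photographs (PSNR ≈ 40–43, mean ΔE ≈ 1.3–2.4
after correction) require the original 507-photo dataset and trained
weights, neither of which is public; this package reproduces the method,
not those tables.

## Scaled-down problem sizes

The test suite exercises the full pipeline at sizes a single CPU handles in
minutes, chosen once as the package's standard desk-scale conditions:

* structural, gradient and metric checks run on tiny configurations
  (2–4 filters, 8×8 inputs) — the topology, and therefore the layer
  counts, are identical to the full model;
* the end-to-end learning check trains a reduced network (8 intermediate /
  16 output channels, same 26-layer topology) on 512 synthetic 64×64
  bluish-cast pairs (304 training pairs after the 60/30/10 by-image split)
  with Adam at learning rate 1e-3–3e-3 for at most 30 epochs, and requires
  the held-out mean ΔE to drop by at least half relative to the biased
  input. The learning rate is higher than the full-scale default because
  the scaled task is hundreds of steps long, not tens of thousands.

## Known limitations

* The renderer emulates color statistics only; no claim is made about real
  photographs.
* Casts are global and single-kind; mixed or spatially varying casts are
  out of scope, as are physically based illuminant spectra.
* The CIELAB transform matches external references to ~0.3 ΔE on saturated
  colors (transform-matrix precision); agreement is exact to 4+ decimals on
  neutrals.
* DCCN per-layer widths and the SDW weight formula are documented
  assumptions where the published descriptions are silent.
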