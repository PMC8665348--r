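---
title: "Sorting and reconstructing defocused phase-contrast cell images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting and reconstructing defocused phase-contrast cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput and time-lapse cell imaging produce thousands of
phase-contrast frames per experiment. Autofocus occasionally fails —
especially on substrates with background texture such as PDMS, where micro
air bubbles and material noise confuse focus algorithms — and a manually
unrecoverable fraction of frames comes out defocused. `refocus` implements a
two-stage remedy:

1. **Sorting.** A small convolutional classifier (here called SDCNN) labels
   each frame focused or defocused from its central 536 × 536 px crop.
2. **Reconstruction.** A residual U-Net with instance normalization
   (ResUNet) restores flagged frames to near-focused appearance at
   subcellular detail.

A synthetic scene and defocus simulator makes the whole pipeline trainable
and testable without any external data, and a Richardson–Lucy deconvolution
baseline is included for comparison.

## The sorting model

The classifier is deliberately simple: four 3 × 3 same-padded convolution
blocks (ReLU, 2 × 2 max-pool), widths 32/64/128/256 by default, a global
average pooling head in place of flattening, and a two-node softmax layer.
One-hot labels follow the convention `[1, 0]` = focused, `[0, 1]` =
defocused. Global average pooling keeps the parameter count under one
million and makes the network applicable to any input side that survives
the pooling stages, so the same weights score 134 px and 536 px inputs.

Training minimizes categorical cross-entropy with SGD, momentum 0.9, batch
size 4, initial learning rate 0.001 halved every five epochs; the
checkpoint with the lowest validation loss within the epoch budget
(default 50) is kept. Transfer learning continues training at a reduced
two-step rate of 2 × 10⁻⁴, dropping to 10⁻⁴ after 25 epochs. Five-fold
cross-validation shuffles the data into five near-equal folds, each serving
once as the validation set. Every image is standardized to mean 0, spread
1 over all pixels and channels jointly before input, with the denominator
floored at `1/sqrt(N)` so constant images map to zeros.

The exact depth and filter widths of the original architecture are not
published; the default spec above is the package's own declaration,
consistent with a basic-layers-only design and sub-hour training times. A
`conv_widths` argument exposes the width stack; desk-scale runs in the
tests use 8/16/32/64.

## The reconstruction model

The ResUNet is a depth-4 valid-convolution U-Net whose double-convolution
stages are replaced by pre-activation residual blocks:

* main path: `Conv3×3(ReLU(IN(Conv3×3(ReLU(IN(x))))))`,
* shortcut: `Conv1×1(ReLU(IN(Crop(x))))`, where `Crop` removes 2 px per
  border — forced by the two valid 3 × 3 convolutions in the main path,
* encoder blocks add a 2 × 2 max-pool of the sum; the pre-pool sum feeds
  the skip connection.

Instance normalization (ε = 10⁻⁵, affine parameters on) normalizes each
image's feature maps independently at both training and inference,
preserving per-image style — the reason the reconstructor takes raw
`[0, 1]` images with no per-image standardization. Upsampling uses 2 × 2
stride-2 transpose convolutions; skips are center-cropped and
concatenated; a final 1 × 1 linear convolution maps to three channels.
Valid convolutions shrink the side by 184 in total: a 572 × 572 input
yields a 388 × 388 output, and the admissible input sides are 204 + 16 m.
To reconstruct a full frame, the input is mirror-padded by 92 px per
border (reflection excluding the edge pixel) and, for frames larger than
388 px, processed by an overlap-tile scheme: output tiles are placed
without blending, flush at the frame edges, each output pixel owned by
exactly one tile.

Training uses SSIM loss (`1 − SSIM`) by default — L1 and the combinatory
loss `L1 + 100·SSIM_loss` are available — with Nadam at its customary
defaults, batch size 2, and checkpoint selection by highest validation
SSIM within 60 epochs (40 for small per-condition datasets). The SSIM
gradient is computed analytically via the adjoint of the valid-mode window
filtering and is verified against finite differences in the tests.

Two numerical choices are the package's own: the final convolution is
zero-initialized with its bias at 0.5, the intensity mid-point — the
standard last-layer zero initialization of residual networks — so the
untrained model outputs a flat mid-gray plane and short trainings spend
their steps on structure rather than unlearning random texture; and
outputs are clipped to
`[0, 1]` at inference while the loss sees the unclipped values. Filter
widths double from `base_width` (64 by default, giving the classical
U-Net dimensioning up to 1024 at the bottleneck); `base_width = 8` gives a
desk-scale model used throughout the tests. A `residual = FALSE` flag
builds the plain-U-Net comparison arm with the same geometry.

## The synthetic data generator

The renderer emulates the statistics of phase-contrast cell images, not
their optics: dark elliptical cell bodies with bright Gaussian halo rings
at the rim, darker nuclei, low-frequency substrate texture (glass < TCPS <
PDMS), PDMS blob artifacts standing in for micro air bubbles, small
per-channel gain differences, and Gaussian sensor noise (s.d. 0.02 by
default). Rendering is bit-reproducible for a fixed seed.

Defocus is modeled as a Gaussian point-spread function with
`sigma_px = sigma_per_um · |d| · (magnification / 100)` plus a contrast
attenuation `exp(−contrast_decay · |d|)` toward the image mean. The
defaults are derived from the acquisition optics rather than tuned: a
10×/0.30-NA objective sampled at 2.7 px/µm has a geometric defocus blur
radius of roughly `NA · d` in the sample plane, whose Gaussian-equivalent
σ is about half — giving `sigma_per_um = 0.4` px/µm at 100×, doubled at
200× where the same axial error defocuses the image more strongly.
`contrast_decay = 0.04` /µm leaves ~45 % of contrast at 20 µm, consistent
with ±20 µm images whose subcellular detail is essentially invisible. With
noise off, blurring conserves the image mean exactly (half-sample
symmetric boundary), and zero distance is the identity.

Dataset protocols mirror the acquisition design: the sorting set is
balanced 1:1 focused/defocused and 1:1 across 100×/200× magnification,
with a 2:1:1 EC/SMC/3T3 cell-type mix and three substrates; defocus
distances default to the σ = 6 px regime at classifier scale (15 µm at
100×, 7.5 µm at 200×) with 1 µm mechanical jitter and random sign.
Crucially, each sorting image is produced the way the workflow sees real
data: rendered, blurred, and noised at native camera pitch (4× the
delivered side, the same pitch as the chip generator) and then
downsampled — so sorter training images and chip-frame crops share their
noise and cell-size statistics by construction, as they do in a real
acquisition. Reconstruction pairs follow
the per-scene protocol of one focused image plus one defocused image per
signed distance (±10, ±20 µm at 100×), jittered but never sign-flipped.
The chip generator emulates a 120-frame autofocused microarray scan with 8
heavily blurred frames; chip frames are native-resolution, so cells span
about four times as many pixels as in classifier-resolution scenes, and
the default blur σ = 24 px corresponds to σ = 6 px after the workflow's
central crop and 4× resize.

What the simulator does **not** reproduce: true phase-contrast optics
(halo formation, shade-off), cell morphology diversity, debris and
artifacts, illumination gradients, or motility. Passing tests therefore
demonstrate that the models and training loops work as specified and that
the task structure (blur detectable, restoration learnable) is intact —
not that the printed large-scale accuracies on real data are reproduced.

## Problem sizes in the tests

The test-suite and acceptance runs use reduced problem sizes chosen to
exercise every code path in minutes on one core: 200 sorting images at
134² (10 epochs, widths 8/16/32/64), 64 reconstruction pairs of 100 px
scenes (network input 284, 5 epochs, `base_width` 8), and a 120-frame chip
at 600² standing in for 1604² acquisitions. The spatial scale reduction is
the package's own choice of desk-scale study conditions; all defaults for
full-scale runs (widths 32–256, `base_width` 64, 50/60 epochs, 388 px
tiles) match the protocol described above.

## The Richardson–Lucy baseline

The classical comparison restores each channel with multiplicative RL
updates `u ← u · ((d / (u ⊛ P)) ⊛ P̂)` for a Gaussian PSF, reflective
boundary handling (avoiding dark frame artifacts; the source protocol is
silent on boundaries), and a 10⁻¹² guard on the division. A per-channel
exhaustive grid search over PSF size, σ, and iteration count scores
candidates by SSIM against a focused reference; without a reference it
falls back to a variance-of-Laplacian sharpness proxy, an extension beyond
reference-based scoring, flagged as such.

## Conventions and degenerate inputs

* Coordinates are row-major; crops use 0-based offsets `floor((H−side)/2)`
  (up-left bias for odd remainders).
* Bilinear resizing aligns half-pixel centers, clamped at the borders.
* "Symmetric" padding for network inputs mirrors **without** repeating the
  edge pixel (`[a,b,c]` padded by 2 → `[c,b,a,b,c,b,a]`); the alternative
  edge-including dialect is used only inside Gaussian blurring, where it
  conserves the image mean exactly. The source protocol does not say which
  dialect it used; this one is fixed for deterministic tests.
* The 16-tile reconstruction augmentation uses offsets {0, 406, 813, 1220}
  per axis. Sixteen 388-px tiles cannot cover a 1608-px frame
  (4 × 388 = 1552), so three 18–19 px strips per axis are left out; only
  the tile count is prescribed by the protocol.
* SSIM uses the standard 11 × 11 Gaussian window, σ 1.5, k₁ = 0.01,
  k₂ = 0.03, dynamic range 1, valid interior only, channels averaged. The
  original SSIM constants are not stated in the source protocol, so
  printed SSIM values elsewhere are not bit-targets.
* ROC curves sweep all distinct thresholds with trapezoidal area, equal to
  the Mann–Whitney pair statistic with ties counted one half.
* Classification ties at probability 0.5 resolve to "focused".
* A constant image standardizes to zeros; empty directories sort to empty
  manifests; unreadable files are skipped with a warning, never silently.

## Known limitations

* Networks run on CPU in compiled R; full-scale training (thousands of
  images, 50–60 epochs) is possible but slow compared to GPU frameworks.
  The architecture, losses, and protocols are faithful; throughput is not.
* The blur-vs-distance law of any real microscope differs from the linear
  Gaussian model; `sigma_per_um` and `contrast_decay` are explicit knobs.
* The exact published layer tables for both networks live in inaccessible
  supplementary material; the defaults here are declared, not inferred.
* Reconstructed images are appropriate for morphology-level measurements
  (coverage, nucleus area, shape), not for pixel-precision quantification.
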