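---
title: "Restoring fast low-resolution two-photon vascular images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring fast low-resolution two-photon vascular images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesselsr)
```

## The problem

Point-scanning multiphoton microscopy builds a 3D image one pixel at a time,
so acquisition time scales with the pixel count. Imaging cortical
vasculature at capillary resolution (512 x 512 pixels over a ~700 um field,
3 um axial steps) is slow enough to limit cohort sizes in chronic studies.
Acquiring at 128 x 128 pixels is up to four times faster per axis scanned,
but the raw images cannot resolve individual capillaries. `vesselsr`
implements the computational alternative: restore the fast low-resolution
(LR) stacks to high-resolution (HR) with a convolutional network trained on
*semi-synthetic* pairs, then quantify how faithfully downstream vascular
morphology survives the round trip.

The package covers five stages, each usable on its own:

1. **Preprocessing** (`preprocess_stack()`): 3D median filter, full-scale
   contrast stretch (FSCS), 16-to-8-bit conversion.
2. **Semi-synthetic pair generation** (`make_single_frame_dataset()`,
   `make_multiframe_dataset()`): noise injection followed by fourfold
   downscaling of real (or phantom) HR frames.
3. **Model fitting** (`pssr()`): a compact residual U-Net with a subpixel
   decoder, trained with MSE.
4. **Restoration metrics** (`psnr()`, `ssim()`, `cnr()`,
   `paired_wilcoxon()`, `bonferroni()`).
5. **Morphology evaluation** (`peak_accuracy_sweep()`, `strand_metrics()`,
   `cdf_pearson_r2()`, `ks_two_sample()`) against ground truth from the
   vascular phantom (`generate_phantom()`).

## Preprocessing

Raw 16-bit stacks are despeckled with a 3D median filter. The filter's
"size [1 1 1]" convention in the originating analysis environment is read
as a per-axis **radius** of 1, i.e. a 3 x 3 x 3 window — a literal 1 x 1 x 1
window would be the identity and could not despeckle anything. Borders are
handled by mirror (symmetric) reflection; the Rcpp implementation is checked
against a brute-force sorted-window oracle in the tests.

FSCS then linearly remaps intensities so the stack fills its whole bit
range, saturating 0.3% of voxels by default. The saturated fraction is
split evenly across the two tails (0.15% per tail), the common convention
for contrast stretching; the split is configurable. Clip bounds are
quantiles over the *entire stack* (not per slice), computed with linear
interpolation between order statistics (R's default type 7). A constant
stack cannot be stretched; it maps to all zeros with a warning rather than
an error so batch runs survive empty frames.

## Semi-synthetic degradation

Training pairs are manufactured from HR frames alone: inject noise, then
downscale fourfold (512 -> 128, or any side divisible by the factor). Noise
comes *before* downscaling, which matters — downscaling averages 16 HR
pixels per LR pixel and reshapes the noise spectrum the same way real
low-resolution acquisition does not; injecting first mimics the reduced
per-pixel signal of fast scans.

Four noise models are available (`noise_config()`), with the parameter
conventions of the environment in which they were tuned:

* `gaussian`: N(0, 0.1^2) on the normalized [0, 1] scale;
* `additive_gaussian`: sigma = 5 quoted on the 8-bit scale (used as 5/255)
  plus a signal-proportional variance term 0.001 * I — the two scales are
  deliberate, not a bug, and both are explicit config fields;
* `poisson`: shot noise with a configurable full-scale photon gain
  (default 50), since a photon budget must be assumed to make a Poisson
  draw meaningful on normalized data;
* `none`: the downscale-only reference.

All injected frames are clipped back to [0, 1] (a saturating sensor).

Multi-frame samples stack five axially consecutive LR frames and target the
HR frame of the middle (third) position; a stack of n frames yields
n - 4 windows and windows never cross stack boundaries. Window construction
is index-based: the physical axial separation of the acquired frames is
whatever the stack metadata says, and the builder makes no assumption about
it.

## The super-resolution network

`model_config()` describes a residual U-Net: a strided residual encoder, a
decoder that returns to the input resolution through learnable subpixel
(pixel-shuffle) convolutions with skip connections at matching scales, then
continues through further subpixel stages until the output is `scale` times
the input side (default 4x, i.e. two extra stages). Deconvolution-style
upsampling produces checkerboard artifacts from uneven kernel overlap;
instead of managing stride lengths, every upsampling stage is followed by a
normalized zero-order-hold (box) blur of width equal to the stage factor,
applied with reflection padding. `subpixel_upsample()` exposes the
building block directly, and the tests verify that a shuffled checkerboard
averages to exactly 0.5 under the box-2 kernel.

Design choices where the architecture was genuinely open:

* **Encoder size.** The full-scale original uses an ImageNet-pretrained
  classifier encoder. Here the default is a compact randomly initialised
  encoder (4 stages, 32 base channels, channel doubling capped at 8x) so
  that training is feasible on a desk CPU; a `weights` hook accepts
  externally trained parameters. The package claims the stated structural
  elements, not architectural equivalence with any particular encoder.
* **Global residual skip** (`global_residual = TRUE`). The network output
  is added to a bilinear interpolation of the (centre) input frame, so the
  convolutional path learns a *correction* to plain interpolation rather
  than the full LR-to-HR mapping. This is standard residual-learning
  practice in super-resolution; without it, a compact model spends a short
  training schedule learning the DC intensity level and converges to a
  near-constant output. It is a trainability device, switchable off.
* **Optimizer.** Adam, with the published learning rates as defaults:
  9e-4 for single-frame and 1e-4 for multi-frame training. The loss is
  MSE; the best-validation checkpoint is returned.
* **Normalization.** The network sees inputs on [0, 1]; predictions are
  clipped to [0, 1] and rescaled to the stack's bit range on output.
* **Multi-frame edges.** Training uses only full windows; inference on a
  whole stack reflects window indices at the stack boundaries so the output
  has one frame per input frame.

The implementation is plain R on BLAS: 3 x 3 convolutions are decomposed
into nine shifted 1 x 1 convolutions (matrix products), the blur is a cached
sparse operator, and a small reverse-mode tape differentiates the
skip-connection graph. Finite-difference gradient checks over every
parameter tensor guard the backward pass (ReLU pre-activations are kept away
from exactly zero in those checks, where the central difference and the
subgradient convention legitimately disagree).

`bilinear_upscale()` is the non-learned baseline: separable bilinear
interpolation with half-pixel-centre alignment (no corner alignment), the
convention stated explicitly so the closed-form oracle test is well defined.

## Metrics

PSNR is `10 log10(R^2 / MSE)` with R defaulting to the bit-range maximum,
not the observed maximum; identical frames give `+Inf`, which is propagated
and excluded from medians with a warning. SSIM uses the standard form with
squared variance terms in the denominator and local statistics under an
11-pixel Gaussian window (sigma 1.5), averaged over valid window positions;
`C1 = (0.01 R)^2`, `C2 = (0.03 R)^2`. CNR is
`(mean(fg) - mean(bg)) / sd(bg)` over caller-supplied masks.

Paired comparisons use the two-sided Wilcoxon signed-rank test with zeros
dropped and mid-ranks for ties (exact null distribution for tie-free
n <= 25, normal approximation with continuity correction otherwise), and
Bonferroni-adjusted thresholds (`alpha / m`; 0.0167 for the three
upscaling-method comparisons). The tests validate both against exhaustive
enumeration oracles on n = 8 samples.

## Segmentation and strand morphology

`peak_accuracy_sweep()` sweeps an intensity threshold (default 256 levels
across the bit range; ties resolved to the lowest threshold) and scores each
segmentation with the weighted accuracy
`0.1 * sensitivity + 0.9 * specificity`. The weights reflect that vascular
foreground occupies only ~5-10% of a volume; balanced accuracy would let a
segmentation trade many foreground errors for few background ones.
LR-derived images are upscaled to the HR grid before segmentation, so all
masks compare on the same grid.

Strand records (centerline + per-point radii, in micrometres) reduce to
four morphology statistics. Their exact definitions are conventions of this
package, stated so the tests are well posed: length is the summed segment
length; mean radius is the trapezoidal length-weighted mean of point radii;
z-direction is the length-weighted mean of `|dz|/|d|` over segments (1 for
a vessel along the optical axis); inverse tortuosity is endpoint chord
distance over path length (1 iff straight — a semicircle gives 2/pi).
Distributions are compared via empirical CDFs: squared Pearson correlation
on the union-of-supports grid, and the two-sample Kolmogorov-Smirnov test on
the raw samples. The Pearson grid choice is documented rather than asserted
as anyone else's; r^2 on CDFs saturates when both curves are near-linear,
which is exactly why the K-S test is reported alongside.

## The phantom

`generate_phantom()` builds a 3D tubular network with known ground truth:
random-walk centerlines with curvature controlled by
`tortuosity_amplitude`, radii wandering inside `radius_range_um`
(2-6 um by default, capillary-to-venule scale), rasterized by a
voxel-centre-inside-radius test (partial volume enters only through the
PSF), an anisotropic Gaussian PSF (0.5 / 0.5 / 2.0 um in x / y / z,
mimicking two-photon optics), and Gaussian background noise calibrated so
the measured CNR hits a target (default 0.94). Calibration inverts the CNR
definition analytically: `sigma = sqrt((contrast / CNR)^2 - var_bg_clean)`,
where the clean background variance accounts for the PSF halo.

Default conditions: 16-bit volumes with voxel spacing (3, 1.37, 1.37) um —
the in-plane value being 700 um / 512 px — foreground fraction targeted at
7.5% (inside the 5-10% band typical of cortical vasculature), background
level 32768 and foreground 39768. The levels sit mid-range deliberately:
at CNR 0.94 the noise standard deviation is about equal to the contrast,
and centring the histogram keeps clipping at the bit-range ends below the
0.001% level, which would otherwise bias the calibration.

What the phantom does *not* emulate: branching topology, flow/motion
artifacts, depth-dependent signal loss, and the intensity heterogeneity of
real dye-labelled plasma. Passing tests on phantom data therefore
demonstrate that the machinery is correct and calibrated, not that any
particular accuracy will be achieved on real tissue.

## Desk-scale evaluation conditions

The test suite and the acceptance script train genuinely but at desk scale:
four phantom volumes of 50 frames at 128 x 128 (three for training, one
held out), additive-Gaussian degradation, and the compact model
(encoder depth 2, 8 base channels, batch size 4, 5 epochs) — roughly 60k
parameters and 250 optimizer steps, a few minutes on one CPU core. Stacks
are preprocessed with the standard chain before pair generation, exactly as
real stacks would be.

Two behavioural findings from these conditions are worth recording:

* The **single-frame model beats bilinear interpolation on held-out median
  PSNR** by a clear margin (~0.5 dB) — the restoration claim survives
  aggressive scaling down.
* **Peak weighted segmentation accuracy is a statistical tie** between the
  trained models and bilinear upscaling (differences of order 1e-4). Both
  are far above the unrestored noisy image, because the LR bottleneck
  itself removes most voxel noise. The decisive segmentation advantage of
  the full-scale multi-frame model in the original study rests on training
  budgets (tens of thousands of pairs) that desk-scale runs cannot emulate;
  the suite therefore asserts the ordering (model >= bilinear) rather than
  a margin.

## Known limitations

* Training is single-threaded CPU R; it is meant for compact models and
  method-level validation, not for reproducing full-scale training runs.
* Checkpoints (`pssr_save()`) are R serialization files, portable across
  platforms but not across deep-learning frameworks.
* The median filter treats even window sizes by averaging the two central
  order statistics; only odd windows (radius form) are used by the
  standard chain.
* `read_stack()` understands plain grayscale multi-page TIFF plus
  ImageJ-style `spacing=` metadata; exotic TIFF variants should be
  converted externally first.
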