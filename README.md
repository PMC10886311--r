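# vesselsr

Super-resolution restoration of two-photon vascular image stacks, with
morphology-aware evaluation.

Point-scanning multiphoton microscopy acquires 3D images of cortical
vasculature pixel by pixel, so a 512 × 512 frame costs up to 16× the dwell
time of a 128 × 128 frame. `vesselsr` restores fast low-resolution stacks to
high resolution with a compact residual U-Net trained on *semi-synthetic*
pairs — real high-resolution frames degraded by noise injection followed by
fourfold downscaling — and then asks the question that matters downstream:
does vascular morphology (segmentation masks, strand length, radius,
orientation, tortuosity) survive the round trip?

It is aimed at microscopy labs and methods developers who want to validate
this class of restoration pipeline end to end without acquired data: a
synthetic 3D tubular-network phantom with ground-truth masks and strand
tables makes every stage testable.

## The method in brief

Given a high-resolution frame $I$ on $[0,1]$, a training pair is
$(D_4(N(I)),\, I)$, where $N$ injects one of four noise models (none,
Poisson, Gaussian $\sigma = 0.1$, or additive Gaussian $\sigma = 5/255$ with
local variance $0.001\,I$) and $D_4$ is fourfold block-mean downscaling.
The network $f_\theta$ is a residual U-Net whose decoder upsamples by
learnable subpixel (pixel-shuffle) convolutions, each followed by a
zero-order-hold box blur to suppress checkerboard artifacts, plus a global
residual skip over bilinear interpolation. Training minimises
$\mathrm{MSE}(f_\theta(\mathrm{LR}), \mathrm{HR})$ with Adam (learning rate
$9\times10^{-4}$ single-frame, $1\times10^{-4}$ multi-frame; the multi-frame
variant feeds five axially consecutive LR frames and predicts the middle
one). Restoration is scored by PSNR $=10\log_{10}(R^2/\mathrm{MSE})$ and
SSIM; segmentation by the weighted accuracy
$0.1\,\mathrm{sensitivity} + 0.9\,\mathrm{specificity}$ at the best
threshold of a sweep (foreground is only ~5–10% of a volume); strand
morphology by CDF-level Pearson $r^2$ and two-sample Kolmogorov–Smirnov
tests, with Wilcoxon signed-rank tests and Bonferroni-adjusted thresholds
for paired method comparisons.

## Worked example

Generate a phantom, degrade it, train the compact single-frame model for a
few epochs, and compare against bilinear upscaling:

```r
library(vesselsr)

# two 30-frame phantom volumes: train on one, hold out the other
vols <- lapply(1:2, function(i)
  generate_phantom(phantom_config(volume_shape = c(30L, 128L, 128L),
                                  seed = 100 + i)))
prep <- lapply(vols, function(v) preprocess_stack(v$image))

cfg   <- noise_config("additive_gaussian")
train <- make_single_frame_dataset(prep[[1]], cfg, seed = 1, stack_id = "v1")
test  <- make_single_frame_dataset(prep[[2]], cfg, seed = 2, stack_id = "v2")

fit <- pssr(train, val = test,
            model = model_config(in_frames = 1, scale = 4,
                                 encoder_depth = 2, base_channels = 8),
            train = train_config(epochs = 5, batch_size = 4, seed = 3))
print(fit)
#> pssr: residual U-Net super-resolution model
#>   input frames: 1, scale: x4, encoder depth: 2, base channels: 8
#>   parameters: 62689; trained 5 epoch(s) on 30 sample(s) (lr 0.0009)
#>   final train MSE: 0.0101483, best val MSE: 0.00988994

ps_model <- sapply(seq_along(test), function(i)
  psnr(predict(fit, test[i])[[1]], test[[i]]$hr, peak = 1))
ps_bl <- sapply(test, function(s)
  psnr(bilinear_upscale(s$lr, 4), s$hr, peak = 1))
median(ps_model) - median(ps_bl)
#> [1] 0.2495998
```

The ~0.25 dB median gain over bilinear interpolation on the held-out volume
is the desk-scale signature of the restoration working (larger training sets
widen it — the acceptance run below trains on three volumes and gains
~0.6 dB); `plot(fit)` shows
the loss history, `upscale(fit, lr_stack)` restores whole stacks
(`image_stack` objects read and written as multi-page TIFF via
`read_stack()` / `write_stack()`).

Downstream fidelity against the phantom's ground truth:

```r
lr_vox <- array(0, c(30, 32, 32))
for (i in 1:30) lr_vox[i, , ] <- test[[i]]$lr * 255
lr_stack <- image_stack(lr_vox, bit_depth = 8L)

peak_accuracy_sweep(upscale(fit, lr_stack), vols[[2]]$truth_mask)$best_accuracy
#> [1] 0.9591501
peak_accuracy_sweep(bilinear_upscale(lr_stack, 4), vols[[2]]$truth_mask)$best_accuracy
#> [1] 0.9579449
```

The restored stack segments at least as well as the bilinear baseline at its
best threshold. Strand-morphology distributions compare through
`strand_table()`, `cdf_pearson_r2()` and `ks_two_sample()`.

`run_pipeline()` chains all stages (phantom → preprocess → synth → train →
upscale → evaluate) from a config list or YAML file and writes a versioned
report; `inst/scripts/vesselsr-pipeline.R` is a thin command-line wrapper
around it.

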