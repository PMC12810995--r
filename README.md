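# needletrack

Instrument tracking in accelerated dynamic MRI, end to end and fully
synthetic. `needletrack` studies a concrete interventional-imaging
question: during in-bore MR-guided prostate biopsy, how aggressively can a
Cartesian acquisition be undersampled — keeping only the central
(autocalibration) k-space lines — while an automatic pipeline still
localizes the tip of the transrectal needle guide to within 5 mm per
frame?

The package provides every stage as tested R code:

* a **synthetic dynamic phantom**: bright pelvis-like background, dark
  cylindrical needle guide moving linearly across an annotated frame
  window, smooth complex coil sensitivities, Rician magnitude noise, and
  full ground truth (per-frame tip positions and masks);
* **k-space machinery**: centred orthonormal FFTs, central-line sampling
  masks with `floor(n/R)` retained lines and acceleration escalation,
  zero-filled reconstruction, RSS coil combination, protocol arithmetic;
* a **temporally recurrent reconstruction network** (bidirectional
  time/iteration recurrence, hard data consistency, `1 - SSIM` loss) with
  hand-written backpropagation over RcppArmadillo convolution kernels;
* a small **2D U-Net segmenter** for the needle guide;
* **principal-axis tip localization**: PCA of the mask coordinates, axis
  endpoints from projection extremes, tip = endpoint nearest the image
  centre;
* **feasibility statistics**: per-sample success rates against the 5 mm
  rule, Wilson score intervals, t-based inference, and moment-matched
  gamma fits
  (`alpha = 4 / skewness^2`, `theta = mean / alpha`).

Results are tibbles throughout and compose with the tidyverse; fitted
summaries have `tidy()`/`glance()` methods and tracking results have a
ggplot2 `autoplot()` heatmap.

## A worked example

Generate a small dynamic sample, track it with ground-truth (oracle)
segmentation across the acceleration ladder, and summarize:

```r
library(needletrack)

cfg <- phantom_config(grid_size = 64, n_coils = 4, n_frames = 20,
                      noise_sigma = 0.01, rng_seed = 7)
sample <- generate_sample(cfg)
sample
#> <dynamic_sample> 20 frames, 4 coil(s), grid 64 @ 1.094 mm, motion frames [7, 13]

res <- run_tracking_experiment(
  sample, experiment_config(methods = "zero_filled"),
  oracle_segmentation = TRUE
)
summarize_experiment(res)
#> # A tibble: 8 x 8
#>       R method      n_samples n_frames mean_success sd_success wilson_lo wilson_hi
#>   <dbl> <chr>           <int>    <int>        <dbl>      <dbl>     <dbl>     <dbl>
#> 1     8 zero_filled         1       20            1          0     0.839         1
#> 2    10 zero_filled         1       20            1          0     0.839         1
#> # ... 12x-25x identical: with perfect segmentation every frame succeeds,
#> #     which isolates reconstruction quality as the thing that breaks tracking
```

With oracle segmentation the tip error stays below one pixel at every
acceleration (`max(res$error_mm)` is about 0.2 mm here), so any tracking
failure in the full pipeline is attributable to reconstruction and
segmentation quality, not to the tip localizer. Swap in trained models to
measure the real thing:

```r
seqs <- generate_recon_training_set(
  20, phantom_config(grid_size = 64, n_coils = 1, n_frames = 5,
                     noise_sigma = 0.01, rng_seed = 1), seed = 41)
recon <- train_recon_model(seqs, crnn_config(rng_seed = 42))

segdat <- generate_seg_training_set(
  4, phantom_config(grid_size = 64, n_coils = 1, n_frames = 8, rng_seed = 2),
  seed = 43, recon_R = c(1, 8, 12))
seg <- train_segmenter(segdat$image, segdat$mask,
                       seg_config(epochs = 12, rng_seed = 44))

res <- run_tracking_experiment(sample, experiment_config(),
                               recon_model = recon, seg_model = seg)
summarize_experiment(res)
autoplot(res, R = 16, method = "crnn")
```

The published statistics that are computable from printed inputs fall out
of the same functions:

```r
t_confidence_interval(1.55, 1.01, 201)
#>       lo       hi
#> 1.409522 1.690478
wilson_interval(10, 10)
#> <wilson_interval> 10/10: [0.7225, 1.0000] at 95%
scan_time(4.56, 320, 5); scan_time(4.68, 68, 60)
#> [1] 7.3
#> [1] 19.09
effective_undersampling(320, 68)
#> [1] 4.7
```

## Repository layout

* `R/`, `src/` — implementation (R plus RcppArmadillo conv kernels)
* `tests/testthat/` — unit, property and acceptance suites
* `vignettes/needle-tracking-methods.Rmd` — the models, their assumptions,
  parameter choices, and known limitations
* `scripts/acceptance.R` — the reproduction script above
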