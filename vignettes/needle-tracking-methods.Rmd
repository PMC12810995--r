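---
title: "Needle-guide tracking in accelerated dynamic MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Needle-guide tracking in accelerated dynamic MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(needletrack)
```

## The problem

In-bore MR-guided prostate biopsy confirms the position of a transrectal
needle guide with repeated imaging, which is slow. Acquiring only the
central (autocalibration, ACS) lines of k-space makes each dynamic frame
fast enough for near-real-time guidance, at the price of heavy aliasing and
blur along the phase-encoding direction. The question this package studies
is: *how far can Cartesian centre-line undersampling be pushed while an
automatic pipeline — reconstruction, segmentation, principal-axis tip
localization — still finds the needle-guide tip to within a clinically
acceptable 5 mm?*

Because raw clinical k-space from such procedures is not public, the
package is driven by a synthetic dynamic phantom that reproduces the
*structure* of the clinical experiment: a fully sampled pre-movement scan,
60 dynamic frames during which the guide moves linearly across an annotated
frame window, and a fully sampled post-movement scan. All statistics
downstream (success rates, Wilson intervals, t-based inference, gamma
moment fits) operate on this structure.

## The synthetic phantom

`phantom_config()` / `generate_sample()` emulate a bright pelvis-like
background with a dark cylindrical needle guide:

* **Background**: a low-pass-filtered Gaussian random field plus two soft
  ellipses (a bright prostate-like body and a darker rectum-like region),
  clipped to `[0, 1]`. The background is *procedural*, not derived from
  patient data; the tracking task only needs realistic guide/background
  contrast and texture, not anatomy.
* **Needle guide**: a signal void (default 90 % suppression) shaped as a
  flat-capped cylinder around the axis segment from base to tip,
  matching the bright-fluid (bSSFP) appearance of a plastic guide. A pixel
  belongs to the mask iff its centre is within the radius of the axis *and*
  its axial projection lies between the endpoints. Flat caps matter: with
  rounded caps the mask would extend ~one radius beyond the tip and the
  principal-axis tip estimate would inherit that bias.
* **Motion**: strictly in-plane and linear from `tip_start` to `tip_end`
  across the annotated window, constant outside it. This matches the
  evaluation model, whose reference trajectory is itself a linear
  interpolation — ground truth and evaluation share the same motion model
  by construction.
* **Coils**: `coil_maps()` returns smooth complex sensitivities (Gaussian
  magnitude bumps around the FOV with gentle phase ramps), normalized so
  the root sum of squares is exactly 1 at every pixel.
* **Noise**: i.i.d. complex Gaussian noise added in k-space, so magnitude
  reconstructions carry Rician noise; at signal-free pixels the magnitude
  is Rayleigh, which the test suite verifies with a Kolmogorov-Smirnov
  test.
* **Geometry defaults** scale with the field of view so the same
  configuration works at the protocol grid (256 px at 1.094 mm/px, 60
  frames, 4 coils) and at the small grids used for CPU experiments
  (64-128 px). The guide's physical radius is not published; the default
  (max of 2 px and 1.2 % of the FOV) keeps the guide aspect ratio well
  above 4:1 so the principal axis is well defined.
* The clinical pre/post scans are 5-slice stacks; the phantom collapses
  them to the central slice because all tracking is 2D in-plane.

Generation is a pure function of the configuration, including its seed:
identical configurations give bit-identical samples.

## K-space machinery

All transforms are centred, orthonormal 2D FFTs (`centered_fft2()`), so
Parseval's identity is exact and the zero-frequency line sits at 0-based
index `grid_size/2`. Phase encoding runs along the row axis; the frequency
axis is always fully sampled, as in a Cartesian parallel-imaging
acquisition.

`make_central_mask(n_phase, R)` retains `floor(n_phase / R)` contiguous
central lines. The floor rule is inferred from the published line counts
(32, 25, 21, 18, 16, 14, 12, 10 for R = 8...25 at 256 lines), which it
reproduces exactly; when the retained count is odd the extra line sits on
the lower-index side of the centre (a convention that had to be fixed —
the symmetric alternative differs by one line). `escalate_mask()`
implements the "zero additional outer ACS lines" protocol and is
guaranteed to equal direct construction at the higher factor.
`zero_fill_reconstruct()` is the baseline: mask, per-coil inverse FFT,
root-sum-of-squares combination.

Intensity scaling (`scale_intensities()`) is affine to `[0, 1]` using the
*global* extrema of a sequence, not per-frame extrema, to preserve temporal
intensity dynamics for the recurrent model; a constant sequence maps to
zeros. The ACS block is centred on the 256-line reconstructed grid (the
acquisition zero-pads to 256 x 256), not the 320-line encoded grid.

## The recurrent reconstruction network

`train_recon_model()` / `reconstruct_sequence()` implement a temporally
recurrent unrolled reconstruction: each of `n_iterations` passes applies
five convolutional units per frame — one bidirectional unit whose hidden
state evolves over both time and iterations, three units recurrent over
iterations, and one plain convolutional unit mapping back to the
two-channel (real/imaginary) image — followed by a residual connection and
*hard* data consistency: the forward transform of the prediction is
overwritten with the measured k-space on every sampled line. Hard (rather
than soft, noise-weighted) consistency is used because no noise-weighting
parameter is published; it guarantees sampled lines are preserved to
machine precision, and at full sampling the reconstruction equals the RSS
image regardless of the weights.

Choices the architecture description leaves open, fixed here:

* **Loss**: `1 - mean SSIM` over the window's frames, with the standard
  11 x 11, sigma 1.5 Gaussian window, K1 = 0.01, K2 = 0.03, dynamic range 1.
  SSIM statistics are computed over the valid interior (no padded
  windows), which makes the zero-variance closed form exact and the
  analytic gradient clean; the gradient is verified against finite
  differences in the tests.
* **Temporal edges**: replicate padding — each output frame is the centre
  result of the window centred on it, with indices clamped at the sequence
  ends. (Within a single window the bidirectional recurrence is *not*
  time-shift invariant — hidden states start at zero at the window edges —
  so the meaningful invariance, verified in the tests, is at the sequence
  level: a constant-in-time sequence reconstructs identically at every
  frame.)
* **Multi-coil handling**: the network runs coil by coil with shared
  weights and per-coil data consistency, and outputs combine by RSS.
  Training uses single-coil complex sequences.
* **Training data**: complex phantom sequences (magnitude-only DICOM-style
  training would discard the phase the data-consistency step needs);
  undersampling is synthesized on the fly at the configured acceleration;
  augmentation applies random horizontal/vertical flips, rotations by
  multiples of 90 degrees, and additional Rician noise (complex Gaussian
  noise in k-space, input only).
* **Optimizer**: Adam at 1e-3, one step per sequence, seeded shuffling;
  unpublished in the source protocol, recorded in `crnn_config()`.

The network, backpropagation (through the data-consistency projector, the
residual connections, and both recurrence directions) and the SSIM loss
gradient are implemented from first principles on top of small
im2col + GEMM convolution kernels (RcppArmadillo); no deep-learning
framework is involved. Every gradient path is checked against central
finite differences in the test suite.

`crnn_config()` defaults to a desk-scale model — 2 iterations, 16 filters,
5-frame windows, 50 epochs — sized for single-CPU experiments on 64 x 64
grids; `crnn_config_full()` is the full-scale preset (10 iterations, 128
filters) with identical code paths.

## Segmentation

A fixed small 2D U-Net (`seg_config()`, `train_segmenter()`, `segment()`)
stands in for a self-configuring segmentation framework: depth-2
encoder/decoder, two 3 x 3 convolutions per level, 2 x 2 max pooling,
nearest-neighbour upsampling, skip connections, trained with binary
cross-entropy plus soft Dice. The self-configuration machinery of the
original is external tooling, not method content; the pipeline only needs
the images-to-mask interface. The foreground probability is thresholded at
0.5; largest-connected-component filtering exists but is off by default.
Training corpora pair reconstructed phantom frames (fully sampled and
undersampled) with ground-truth masks, plus guide-free background frames
paired with empty masks so the model learns to stay silent when no
instrument is present. Data splits (`split_dataset()`) are at the level of
synthetic subjects (80/20 by default), never frames.

## Tip localization and the reference trajectory

`pca_tip()` computes the centroid of the foreground pixel coordinates, the
2 x 2 coordinate covariance and its principal eigenvector; the axis
endpoints are the extreme scalar projections of the foreground pixels onto
the eigenvector (robust to ragged mask edges, unlike a bounding box), and
the tip is the endpoint nearer the image centre — which also resolves the
eigenvector's sign ambiguity. Pixel centres sit at `(i + 0.5) * spacing`
mm for 0-based index `i`, and the image centre at
`grid_size * spacing / 2`. Empty or directionally degenerate masks
(eigenvalue gap below 1e-9, e.g. an isotropic disc) yield an *invalid*
estimate rather than an error, so a dropout frame scores as a tracking
failure — every frame is scored.

The reference trajectory interpolates linearly between the tip estimates
of the pre- and post-movement segmentations across the annotated motion
window and is constant outside it. The per-frame ITP (instrument tip
prediction) error is the Euclidean distance in mm to this reference; an
error of exactly 5 mm counts as failure.

## Statistics

* `success_rate()`: fraction of non-excluded frames with error strictly
  below threshold. Frame exclusions are input annotations (unreadable
  frames), never auto-detected.
* `wilson_interval()`: Wilson score interval; better small-sample
  behaviour than the Wald interval, and the reason published lower bounds
  look pessimistic at high success rates with few samples. In
  `summarize_experiment()` the interval is computed on the frames pooled
  across samples at each acceleration (one defensible reading of the
  protocol — the published bounds are not reproducible from any obvious
  (k, n) choice, so the generic (k, n) operation is exposed and this
  reading documented rather than guessed at).
* Per-sample success-rate dispersion uses the sample (n-1) standard
  deviation.
* `t_confidence_interval()` / `one_sample_t_test()`: standard t-based
  interval and the one-sided test of mean error below 5 mm (via
  `stats::t.test`); a zero-variance sample returns a flagged degenerate
  result rather than an error.
* `gamma_moment_fit()`: `Gamma(alpha, theta)` by moment matching
  `alpha = 4 / skewness^2`, `theta = mean / alpha`, with the adjusted
  Fisher-Pearson sample skewness (the estimator is not specified in the
  source; the adjusted form is the common default). Non-positive skewness
  is an error.

## Desk-scale experiment sizes

The experiments the tests and the acceptance script run are sized for a
single CPU; all use the same code paths as the protocol-scale
configuration:

* reconstruction training: 20 sequences of 5 frames at 64 x 64, single
  coil, 8x undersampling, 50 epochs (about 12 minutes); the acceptance
  script uses 16 sequences and 30 epochs, which is already enough to beat
  the zero-filled baseline on held-out data;
* segmentation training: 4 synthetic subjects, frames reconstructed at
  R in {1, 8, 12}, 12 epochs;
* tracking: a fixed 20-frame, 64 x 64 phantom swept over the full
  acceleration ladder 8x...25x.

## What passing tests do and do not show

The phantom reproduces the *geometry and sampling structure* of the
clinical experiment — centre-line undersampling, linear guide motion,
Rician noise, multi-coil combination — so it can validate the machinery:
mask arithmetic, data consistency, tip localization, statistics, and the
qualitative ordering that a temporally recurrent reconstruction tracks at
higher accelerations than zero-filling. It does not contain real anatomy,
through-plane motion, banding or eddy-current artifacts, scanner phase, or
human annotation noise, so absolute success percentages on the phantom do
not transfer to clinical data, and the package makes no claim to reproduce
published clinical success rates.

## Known limitations

* Motion is linear and in-plane by design; the evaluation model assumes
  the same, so non-linear motion violations are out of scope.
* The recurrent model is trained per configuration; no pretrained clinical
  weights exist or are emulated.
* The Wilson interval's (k, n) pooling choice is a documented reading, not
  a reproduction of the published bounds (see above).
* GRAPPA unaliasing is deliberately absent: only ACS-line retention is
  modelled, matching the evaluation protocol of the source experiment.
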