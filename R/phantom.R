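#' Configuration for the synthetic dynamic needle-guide phantom
#'
#' Defines one synthetic "sample" mimicking a dynamic needle-guide movement
#' acquisition: a fully sampled pre-movement scan, `n_frames` dynamic
#' multi-coil k-space frames during which a dark cylindrical needle guide
#' moves linearly in-plane from `tip_start` to `tip_end` over the annotated
#' `move_window`, and a fully sampled post-movement scan. The defaults
#' reproduce the protocol geometry of a 256 x 256 reconstruction at
#' 1.094 mm in-plane resolution with 60 dynamic frames; tests use smaller
#' grids via `grid_size`.
#'
#' Geometry defaults that are `NULL` are derived from the field of view
#' (`grid_size * pixel_spacing_mm`): the guide enters from the lower-right
#' edge and advances along its own axis toward the image centre, so the tip
#' is always the axis endpoint nearest the centre (the convention the tip
#' localizer relies on).
#'
#' @param grid_size Pixels per side (even). Default 256.
#' @param pixel_spacing_mm In-plane resolution in mm/pixel. Default 1.094.
#' @param n_coils Number of receive coils. Default 4.
#' @param n_frames Number of dynamic frames. Default 60.
#' @param move_window Inclusive 1-based frame interval `c(start, end)` of the
#'   guide motion; default is the middle third of the sequence.
#' @param guide_radius_mm Cylinder radius (mm); default scales with the FOV.
#' @param guide_length_mm Visible guide length (mm); default `0.30 * FOV`.
#' @param tip_start,tip_end In-plane tip positions `c(row_mm, col_mm)`.
#' @param noise_sigma Standard deviation of the complex Gaussian k-space
#'   noise per real/imaginary component, relative to unit signal. Default
#'   0.02.
#' @param guide_contrast Fractional signal suppression inside the guide
#'   (1 = complete void). Default 0.9.
#' @param background_amplitude Multiplier on the procedural background
#'   (0 gives a signal-free sample, useful for noise-statistics checks).
#' @param texture_smoothness Low-pass cutoff of the background random field
#'   as a fraction of the grid Nyquist. Default 0.08.
#' @param excluded_frames Integer frame indices annotated as unreadable;
#'   carried through to the tracking statistics. Default none.
#' @param rng_seed Integer seed; generation is a pure function of the
#'   configuration including this seed.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(grid_size = 256, pixel_spacing_mm = 1.094,
                           n_coils = 4, n_frames = 60, move_window = NULL,
                           guide_radius_mm = NULL, guide_length_mm = NULL,
                           tip_start = NULL, tip_end = NULL,
                           noise_sigma = 0.02, guide_contrast = 0.9,
                           background_amplitude = 1,
                           texture_smoothness = 0.08,
                           excluded_frames = integer(0), rng_seed = 1L) {
  stopifnot(grid_size %% 2 == 0, grid_size >= 16, pixel_spacing_mm > 0,
            n_coils >= 1, n_frames >= 1, noise_sigma >= 0,
            guide_contrast >= 0, guide_contrast <= 1)
  fov <- grid_size * pixel_spacing_mm
  if (is.null(move_window)) {
    move_window <- c(max(1L, round(n_frames / 3)), round(2 * n_frames / 3))
  }
  stopifnot(length(move_window) == 2, move_window[1] >= 1,
            move_window[1] <= move_window[2], move_window[2] <= n_frames)
  if (is.null(guide_radius_mm)) {
    guide_radius_mm <- max(2 * pixel_spacing_mm, 0.012 * fov)
  }
  if (is.null(guide_length_mm)) guide_length_mm <- 0.28 * fov
  if (is.null(tip_start)) tip_start <- fov * c(0.58, 0.64)
  if (is.null(tip_end)) tip_end <- fov * c(0.50, 0.52)
  stopifnot(guide_radius_mm > 0, guide_length_mm > 0,
            length(tip_start) == 2, length(tip_end) == 2,
            all(excluded_frames >= 1), all(excluded_frames <= n_frames))
  structure(
    list(grid_size = as.integer(grid_size),
         pixel_spacing_mm = pixel_spacing_mm, n_coils = as.integer(n_coils),
         n_frames = as.integer(n_frames),
         move_window = as.integer(move_window),
         guide_radius_mm = guide_radius_mm,
         guide_length_mm = guide_length_mm,
         tip_start = as.numeric(tip_start), tip_end = as.numeric(tip_end),
         noise_sigma = noise_sigma, guide_contrast = guide_contrast,
         background_amplitude = background_amplitude,
         texture_smoothness = texture_smoothness,
         excluded_frames = as.integer(excluded_frames),
         rng_seed = as.integer(rng_seed)),
    class = "phantom_config"
  )
}

#' Smooth complex coil sensitivity maps
#'
#' Deterministic set of `n_coils` spatially smooth complex sensitivity maps
#' (Gaussian magnitude profiles centred around the field of view with gentle
#' per-coil phase ramps), normalized so the root sum of squares is exactly 1
#' at every pixel.
#'
#' @param n_coils Number of coils (`>= 1`).
#' @param grid_size Pixels per side.
#' @return Complex array `grid_size x grid_size x n_coils`.
#' @export
coil_maps <- function(n_coils, grid_size) {
  stopifnot(n_coils >= 1, grid_size >= 2)
  if (n_coils == 1) {
    return(array(1 + 0i, dim = c(grid_size, grid_size, 1L)))
  }
  g <- grid_size
  idx <- seq_len(g) - 0.5
  rows <- matrix(idx, g, g)
  cols <- matrix(idx, g, g, byrow = TRUE)
  maps <- array(0 + 0i, dim = c(g, g, n_coils))
  sigma <- 0.65 * g
  for (c in seq_len(n_coils)) {
    ang <- 2 * pi * (c - 1) / n_coils + pi / n_coils
    ctr <- g / 2 + 0.55 * g * c(cos(ang), sin(ang))
    mag <- exp(-((rows - ctr[1])^2 + (cols - ctr[2])^2) / (2 * sigma^2))
    ramp <- 0.6 * pi / g * (cos(ang) * rows + sin(ang) * cols)
    maps[, , c] <- mag * exp(1i * ramp)
  }
  rss <- sqrt(apply(Mod(maps)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / rss
  maps
}

#' Rasterize a cylindrical needle guide into a binary mask
#'
#' A pixel belongs to the mask iff its centre lies inside the hypothetical
#' cylindrical region around the axis segment from `base_mm` to `tip_mm`:
#' perpendicular distance to the axis at most `radius_mm` and axial
#' projection between the two endpoints (flat end caps, so the mask does not
#' extend beyond the tip — the tip localizer depends on this). A degenerate
#' zero-length axis yields a disc around `base_mm`. Pixel centres sit at
#' `(i + 0.5) * spacing` for 0-based index `i`. An empty result raises a
#' warning rather than an error.
#'
#' @param base_mm,tip_mm Segment endpoints `c(row_mm, col_mm)`.
#' @param radius_mm Cylinder radius in mm (`> 0`).
#' @param spacing mm per pixel.
#' @param grid_size Pixels per side.
#' @return Logical `grid_size x grid_size` matrix.
#' @export
rasterize_guide_mask <- function(base_mm, tip_mm, radius_mm, spacing,
                                 grid_size) {
  stopifnot(radius_mm > 0, spacing > 0)
  idx <- (seq_len(grid_size) - 0.5) * spacing
  rows <- matrix(idx, grid_size, grid_size)
  cols <- matrix(idx, grid_size, grid_size, byrow = TRUE)
  v <- tip_mm - base_mm
  l2 <- sum(v^2)
  if (l2 == 0) {
    d2 <- (rows - base_mm[1])^2 + (cols - base_mm[2])^2
    mask <- d2 <= radius_mm^2
  } else {
    t <- ((rows - base_mm[1]) * v[1] + (cols - base_mm[2]) * v[2]) / l2
    d2 <- (rows - (base_mm[1] + t * v[1]))^2 +
      (cols - (base_mm[2] + t * v[2]))^2
    mask <- d2 <= radius_mm^2 & t >= 0 & t <= 1
  }
  if (!any(mask)) {
    warning("rasterized guide mask is empty (radius below the pixel grid)")
  }
  mask
}

# linear in-plane tip motion: constant outside the annotated window
tip_at_frame <- function(cfg, f) {
  s <- cfg$move_window[1]
  e <- cfg$move_window[2]
  if (f < s) return(cfg$tip_start)
  if (f >= e) return(cfg$tip_end)
  cfg$tip_start + (f - s) / (e - s) * (cfg$tip_end - cfg$tip_start)
}

# procedural pelvis-like background: low-pass random field plus ellipses,
# bright relative to the guide void, values in [0, 1]
phantom_background <- function(cfg) {
  g <- cfg$grid_size
  noise <- matrix(stats::rnorm(g * g), g, g)
  fr <- (seq_len(g) - 1 - g / 2) / g
  r2 <- outer(fr^2, fr^2, "+")
  lp <- exp(-r2 / (2 * cfg$texture_smoothness^2))
  field <- Re(centered_ifft2(centered_fft2(noise) * lp))
  field <- (field - min(field)) / max(1e-12, diff(range(field)))
  idx <- seq_len(g) - 0.5
  rows <- matrix(idx, g, g)
  cols <- matrix(idx, g, g, byrow = TRUE)
  bg <- 0.45 + 0.3 * field
  # two soft ellipses emulating prostate / rectum contrast
  e1 <- ((rows - 0.45 * g) / (0.22 * g))^2 + ((cols - 0.5 * g) / (0.28 * g))^2
  e2 <- ((rows - 0.68 * g) / (0.10 * g))^2 + ((cols - 0.62 * g) / (0.12 * g))^2
  bg <- bg + 0.25 * exp(-e1^2) - 0.2 * exp(-e2^2)
  pmin(pmax(bg, 0), 1) * cfg$background_amplitude
}

guide_axis_unit <- function(cfg) {
  v <- cfg$tip_end - cfg$tip_start
  if (sum(v^2) > 0) v / sqrt(sum(v^2)) else c(-1, -1) / sqrt(2)
}

check_guide_in_fov <- function(cfg, tip, base, frame_label) {
  fov <- cfg$grid_size * cfg$pixel_spacing_mm
  pts <- rbind(tip, base)
  if (any(pts < cfg$guide_radius_mm) || any(pts > fov - cfg$guide_radius_mm)) {
    stop("needle guide extends outside the field of view at frame ",
         frame_label)
  }
}

#' Generate one synthetic dynamic needle-guide sample
#'
#' Produces the full unit of the tracking experiments: a fully sampled
#' pre-movement multi-coil k-space scan, `n_frames` fully sampled dynamic
#' frames during which the guide tip moves linearly across the annotated
#' window (undersampling is applied downstream), a fully sampled
#' post-movement scan, and complete ground truth (per-frame tip positions
#' and rasterized guide masks). K-space is the centred orthonormal Fourier
#' transform of the coil-weighted complex image plus i.i.d. complex Gaussian
#' noise, so magnitude reconstructions carry Rician noise. Identical
#' configurations (including the seed) give bit-identical samples.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `dynamic_sample`: a list with `pre_kspace`,
#'   `post_kspace` (complex `N x N x n_coils`), `dyn_kspace` (complex
#'   `N x N x n_coils x n_frames`), `truth_tips` (tibble `frame`, `row_mm`,
#'   `col_mm`), `truth_masks` (logical `N x N x n_frames`),
#'   `truth_pre_mask`, `truth_post_mask`, `move_window`, `excluded_frames`,
#'   `spacing`, and the originating `config`.
#' @export
generate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  g <- cfg$grid_size
  sp <- cfg$pixel_spacing_mm
  maps <- coil_maps(cfg$n_coils, g)
  axis <- guide_axis_unit(cfg)
  withr::with_seed(cfg$rng_seed, {
    bg <- phantom_background(cfg)
    frame_kspace <- function(tip, label) {
      base <- tip - cfg$guide_length_mm * axis
      check_guide_in_fov(cfg, tip, base, label)
      mask <- rasterize_guide_mask(base, tip, cfg$guide_radius_mm, sp, g)
      img <- bg * (1 - cfg$guide_contrast * mask)
      ks <- array(0 + 0i, dim = c(g, g, cfg$n_coils))
      for (c in seq_len(cfg$n_coils)) {
        k <- centered_fft2(maps[, , c] * img)
        if (cfg$noise_sigma > 0) {
          k <- k + cfg$noise_sigma *
            (matrix(stats::rnorm(g * g), g, g) +
               1i * matrix(stats::rnorm(g * g), g, g))
        }
        ks[, , c] <- k
      }
      list(kspace = ks, mask = mask)
    }
    dyn <- array(0 + 0i, dim = c(g, g, cfg$n_coils, cfg$n_frames))
    truth_masks <- array(FALSE, dim = c(g, g, cfg$n_frames))
    tips <- matrix(0, cfg$n_frames, 2)
    for (f in seq_len(cfg$n_frames)) {
      tip <- tip_at_frame(cfg, f)
      fr <- frame_kspace(tip, f)
      dyn[, , , f] <- fr$kspace
      truth_masks[, , f] <- fr$mask
      tips[f, ] <- tip
    }
    pre <- frame_kspace(cfg$tip_start, "pre")
    post <- frame_kspace(cfg$tip_end, "post")
  })
  structure(
    list(pre_kspace = pre$kspace, dyn_kspace = dyn,
         post_kspace = post$kspace,
         truth_tips = tibble::tibble(frame = seq_len(cfg$n_frames),
                                     row_mm = tips[, 1], col_mm = tips[, 2]),
         truth_masks = truth_masks,
         truth_pre_mask = pre$mask, truth_post_mask = post$mask,
         move_window = cfg$move_window,
         excluded_frames = cfg$excluded_frames,
         spacing = sp, config = cfg),
    class = "dynamic_sample"
  )
}

#' @export
print.dynamic_sample <- function(x, ...) {
  cat("<dynamic_sample> ", dim(x$dyn_kspace)[4], " frames, ",
      dim(x$dyn_kspace)[3], " coil(s), grid ", dim(x$dyn_kspace)[1],
      " @ ", signif(x$spacing, 4), " mm, motion frames [",
      x$move_window[1], ", ", x$move_window[2], "]\n", sep = "")
  invisible(x)
}

#' Training corpora from the phantom
#'
#' `generate_recon_training_set()` builds short fully sampled single-coil
#' image sequences (one sliding window each) with randomized guide geometry,
#' for training the recurrent reconstruction network; undersampling is
#' synthesized on the fly during training. `generate_seg_training_set()`
#' builds (image, mask) pairs from reconstructed phantom frames at one or
#' more acceleration factors, grouped by synthetic subject for
#' patient-level data splits.
#'
#' @param n_sequences,n_subjects Corpus size.
#' @param cfg Template [phantom_config()]; geometry is jittered per
#'   sequence/subject around this template.
#' @param seed Integer seed for the corpus (independent of `cfg$rng_seed`).
#' @param recon_R Acceleration factors at which segmentation training images
#'   are reconstructed (zero-filled); `1` means fully sampled.
#' @param negatives Also emit guide-free background frames paired with empty
#'   masks (one negative per subject and acceleration), so the segmenter
#'   learns to stay silent when no instrument is present. Default `TRUE`.
#' @return `generate_recon_training_set()`: list of sequences, each a list
#'   of real-valued `[0, 1]` frame matrices. `generate_seg_training_set()`:
#'   tibble with columns `subject`, `frame`, `R`, and list-columns `image`
#'   and `mask`.
#' @export
generate_recon_training_set <- function(n_sequences, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"), n_sequences >= 1)
  fov <- cfg$grid_size * cfg$pixel_spacing_mm
  withr::with_seed(seed, {
    specs <- lapply(seq_len(n_sequences), function(s) {
      list(jit_s = stats::runif(2, -0.04, 0.04) * fov,
           jit_e = stats::runif(2, -0.04, 0.04) * fov,
           seed = sample.int(2^30, 1))
    })
  })
  lapply(specs, function(sp) {
    cfg_s <- cfg
    cfg_s$n_coils <- 1L
    cfg_s$tip_start <- cfg$tip_start + sp$jit_s
    cfg_s$tip_end <- cfg$tip_end + sp$jit_e
    cfg_s$move_window <- c(1L, cfg$n_frames)
    cfg_s$rng_seed <- sp$seed
    smp <- generate_sample(cfg_s)
    frames <- lapply(seq_len(cfg$n_frames), function(f) {
      Mod(centered_ifft2(smp$dyn_kspace[, , 1, f]))
    })
    scale_intensities(frames)
  })
}

#' @rdname generate_recon_training_set
#' @export
generate_seg_training_set <- function(n_subjects, cfg, seed = 1L,
                                      recon_R = c(1, 8), negatives = TRUE) {
  stopifnot(inherits(cfg, "phantom_config"), n_subjects >= 1)
  fov <- cfg$grid_size * cfg$pixel_spacing_mm
  withr::with_seed(seed, {
    specs <- lapply(seq_len(n_subjects), function(s) {
      list(jit_s = stats::runif(2, -0.04, 0.04) * fov,
           jit_e = stats::runif(2, -0.04, 0.04) * fov,
           seed = sample.int(2^30, 1))
    })
  })
  rows <- purrr::imap(specs, function(sp, subj) {
    cfg_s <- cfg
    cfg_s$tip_start <- cfg$tip_start + sp$jit_s
    cfg_s$tip_end <- cfg$tip_end + sp$jit_e
    cfg_s$rng_seed <- sp$seed
    smp <- generate_sample(cfg_s)
    cfg_neg <- cfg_s
    cfg_neg$guide_contrast <- 0 # same anatomy, no visible instrument
    smp_neg <- if (negatives) generate_sample(cfg_neg) else NULL
    empty <- matrix(FALSE, cfg$grid_size, cfg$grid_size)
    purrr::map(recon_R, function(R) {
      msk <- make_central_mask(cfg$grid_size, R)
      imgs <- lapply(seq_len(cfg$n_frames), function(f) {
        zero_fill_reconstruct(smp$dyn_kspace[, , , f, drop = TRUE], msk)
      })
      imgs <- scale_intensities(imgs)
      out <- tibble::tibble(subject = subj, frame = seq_len(cfg$n_frames),
                            R = R, image = imgs,
                            mask = lapply(seq_len(cfg$n_frames),
                                          function(f) smp$truth_masks[, , f]))
      if (negatives) {
        neg_img <- scale_intensities(
          zero_fill_reconstruct(smp_neg$dyn_kspace[, , , 1, drop = TRUE], msk))
        out <- dplyr::bind_rows(out, tibble::tibble(
          subject = subj, frame = NA_integer_, R = R,
          image = list(neg_img), mask = list(empty)
        ))
      }
      out
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
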