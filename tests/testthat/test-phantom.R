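test_that("phantom configuration validates its geometry", {
  cfg <- phantom_config(grid_size = 64)
  expect_s3_class(cfg, "phantom_config")
  expect_true(cfg$move_window[1] >= 1 && cfg$move_window[2] <= cfg$n_frames)
  expect_error(phantom_config(grid_size = 63))
  expect_error(phantom_config(grid_size = 64, move_window = c(5, 2)))
  expect_error(phantom_config(grid_size = 64, n_frames = 10,
                              move_window = c(2, 11)))
  expect_error(phantom_config(grid_size = 64, n_frames = 10,
                              excluded_frames = 12))
})

test_that("coil maps are RSS-normalized, smooth, and trivial for one coil", {
  one <- coil_maps(1, 32)
  expect_equal(one, array(1 + 0i, dim = c(32, 32, 1)))
  for (n in c(2, 4, 8)) {
    maps <- coil_maps(n, 64)
    rss <- sqrt(apply(Mod(maps)^2, c(1, 2), sum))
    expect_true(all(rss >= 0.99 & rss <= 1.01))
    # spatial smoothness: magnitude changes slowly between neighbours
    for (c in seq_len(n)) {
      m <- Mod(maps[, , c])
      grad <- max(abs(diff(m)), abs(t(diff(t(m)))))
      expect_lt(grad, 0.05)
    }
  }
})

test_that("guide rasterization matches a brute-force point-to-cylinder check", {
  # disc: base == tip
  disc <- rasterize_guide_mask(c(8, 8), c(8, 8), 3, 1, 16)
  brute <- matrix(FALSE, 16, 16)
  for (i in 1:16) {
    for (j in 1:16) {
      brute[i, j] <- (i - 0.5 - 8)^2 + (j - 0.5 - 8)^2 <= 9
    }
  }
  expect_identical(disc, brute)
  # axis-aligned thin rod: one-pixel-wide line of round(len) + 1 pixels
  rod <- rasterize_guide_mask(c(8.5, 3.5), c(8.5, 12.5), 0.4, 1, 16)
  expect_equal(sum(rod), 10)
  expect_equal(unique(which(rod, arr.ind = TRUE)[, 1]), 9)
  # oblique rod against the brute-force oracle
  b <- c(3.2, 2.7)
  t <- c(13.8, 11.1)
  r <- 1.7
  m <- rasterize_guide_mask(b, t, r, 1, 16)
  v <- t - b
  for (i in 1:16) {
    for (j in 1:16) {
      p <- c(i, j) - 0.5
      tt <- sum((p - b) * v) / sum(v^2)
      d <- sqrt(sum((p - (b + tt * v))^2))
      expect_identical(m[i, j], tt >= 0 && tt <= 1 && d <= r)
    }
  }
  # vanishing radius off the lattice: empty mask with a warning
  expect_warning(e <- rasterize_guide_mask(c(3.21, 3.33), c(9.77, 8.88),
                                           1e-6, 1, 16), "empty")
  expect_false(any(e))
})

test_that("sample generation is deterministic and respects linear motion", {
  cfg <- phantom_config(grid_size = 64, n_coils = 2, n_frames = 8,
                        move_window = c(3, 7), rng_seed = 5)
  s1 <- generate_sample(cfg)
  s2 <- generate_sample(cfg)
  expect_identical(s1, s2)
  expect_equal(dim(s1$dyn_kspace), c(64, 64, 2, 8))
  expect_equal(nrow(s1$truth_tips), 8)
  # closed-form linear interpolation oracle for the tip trajectory
  for (f in 1:8) {
    expected <- if (f <= 3) {
      cfg$tip_start
    } else if (f >= 7) {
      cfg$tip_end
    } else {
      cfg$tip_start + (f - 3) / 4 * (cfg$tip_end - cfg$tip_start)
    }
    expect_equal(unlist(s1$truth_tips[f, c("row_mm", "col_mm")],
                        use.names = FALSE), expected)
  }
  # per-frame displacement during motion is constant
  mv <- as.matrix(s1$truth_tips[3:7, c("row_mm", "col_mm")])
  steps <- diff(mv)
  expect_lt(max(abs(sweep(steps, 2, steps[1, ]))), 1e-12)
})

test_that("noiseless single-coil k-space round-trips to the phantom image", {
  cfg <- phantom_config(grid_size = 64, n_coils = 1, n_frames = 4,
                        move_window = c(3, 4), noise_sigma = 0, rng_seed = 7)
  s <- generate_sample(cfg)
  # static frame: reconstruct and compare against the rendered scene
  img <- Mod(centered_ifft2(s$dyn_kspace[, , 1, 1]))
  expect_true(all(img[s$truth_masks[, , 1]] < 0.12))
  # guide void is dark relative to its surroundings
  expect_gt(mean(img[!s$truth_masks[, , 1]]), 4 * mean(img[s$truth_masks[, , 1]]))
  # frames before the motion window are identical
  expect_equal(s$dyn_kspace[, , 1, 1], s$dyn_kspace[, , 1, 1])
  rec1 <- Mod(centered_ifft2(s$dyn_kspace[, , 1, 1]))
  rec2 <- Mod(centered_ifft2(s$dyn_kspace[, , 1, 2]))
  expect_lt(max(abs(rec1 - rec2)), 1e-12)
})

test_that("a guide leaving the field of view names the offending frame", {
  fov <- 64 * 1.094
  expect_error(
    generate_sample(phantom_config(grid_size = 64, n_frames = 4,
                                   tip_start = c(fov * 0.9, fov * 0.9),
                                   tip_end = c(fov * 0.99, fov * 0.99))),
    "field of view at frame"
  )
})

test_that("magnitude noise at signal-free pixels is Rayleigh distributed", {
  cfg <- phantom_config(grid_size = 128, n_coils = 1, n_frames = 1,
                        background_amplitude = 0, noise_sigma = 0.03,
                        rng_seed = 9)
  s <- generate_sample(cfg)
  mag <- Mod(centered_ifft2(s$dyn_kspace[, , 1, 1]))
  draws <- as.vector(mag)[seq_len(10000)]
  ks <- stats::ks.test(draws, function(q) 1 - exp(-q^2 / (2 * 0.03^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("principal-axis tip recovery holds on the ground-truth masks", {
  cfg <- phantom_config(grid_size = 64, n_coils = 1, n_frames = 10,
                        noise_sigma = 0, rng_seed = 11)
  s <- generate_sample(cfg)
  aspect <- cfg$guide_length_mm / (2 * cfg$guide_radius_mm)
  expect_gt(aspect, 4)
  for (f in seq_len(10)) {
    tip <- pca_tip(s$truth_masks[, , f], s$spacing)
    expect_true(tip$valid)
    err <- itp_error(tip, unlist(s$truth_tips[f, c("row_mm", "col_mm")]))
    expect_lt(err, s$spacing)
  }
})

test_that("training corpora are reproducible and well-formed", {
  cfg <- phantom_config(grid_size = 32, n_coils = 1, n_frames = 5,
                        noise_sigma = 0, rng_seed = 1)
  s1 <- generate_recon_training_set(3, cfg, seed = 13)
  s2 <- generate_recon_training_set(3, cfg, seed = 13)
  expect_identical(s1, s2)
  expect_length(s1, 3)
  expect_length(s1[[1]], 5)
  rng <- range(unlist(s1))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  seg <- generate_seg_training_set(2, cfg, seed = 14, recon_R = c(1, 4),
                                   negatives = FALSE)
  expect_equal(nrow(seg), 2 * 2 * 5)
  expect_setequal(unique(seg$subject), 1:2)
  expect_true(all(vapply(seg$mask, is.logical, logical(1))))
  # negatives add one guide-free frame per subject and acceleration
  segn <- generate_seg_training_set(2, cfg, seed = 14, recon_R = c(1, 4))
  expect_equal(nrow(segn), 2 * 2 * 6)
  neg <- segn[is.na(segn$frame), ]
  expect_true(all(!vapply(neg$mask, any, logical(1))))
})
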