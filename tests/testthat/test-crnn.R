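test_that("data consistency overwrites exactly the sampled lines", {
  set.seed(31)
  g <- 32
  pred <- matrix(rnorm(g * g), g) + 1i * matrix(rnorm(g * g), g)
  samp <- matrix(rnorm(g * g), g) + 1i * matrix(rnorm(g * g), g)
  m <- make_central_mask(g, 4)
  out <- data_consistency(pred, samp, m)
  expect_identical(out[m$retained, ], samp[m$retained, ])
  expect_identical(out[!m$retained, ], pred[!m$retained, ])
  expect_identical(data_consistency(pred, samp, make_central_mask(g, 1)), samp)
  empty_ish <- make_central_mask(g, g) # one line survives; rest is pred
  out2 <- data_consistency(pred, samp, empty_ish)
  expect_identical(out2[!empty_ish$retained, ], pred[!empty_ish$retained, ])
  expect_error(data_consistency(pred[1:16, 1:16], samp, m))
})

test_that("a zero-weight network reduces to the zero-filled reconstruction", {
  cfg <- crnn_config(n_iterations = 2, n_filters = 4, window_length = 3)
  g <- 32
  set.seed(32)
  imgs <- lapply(1:3, function(t) matrix(runif(g * g), g))
  mask <- make_central_mask(g, 4)
  k_s <- lapply(imgs, function(m) apply_mask(centered_fft2(m), mask))
  zf <- lapply(k_s, centered_ifft2)
  w0 <- needletrack:::init_crnn_weights(cfg, zero = TRUE)
  fw <- needletrack:::crnn_forward(zf, k_s, mask, w0, cfg)
  for (t in 1:3) {
    expect_lt(max(Mod(needletrack:::ch_to_cplx(fw$out[[t]]) - zf[[t]])), 1e-12)
  }
})

test_that("reconstruction at R = 1 equals the RSS image for any weights", {
  cfg <- crnn_config(n_iterations = 2, n_filters = 4, window_length = 3)
  g <- 32
  s <- generate_sample(phantom_config(grid_size = g, n_coils = 2, n_frames = 3,
                                      noise_sigma = 0.01, rng_seed = 33))
  full <- make_central_mask(g, 1)
  w <- withr::with_seed(34, needletrack:::init_crnn_weights(cfg))
  model <- structure(list(weights = w, cfg = cfg,
                          loss_trace = tibble::tibble(epoch = 1, loss = 1)),
                     class = "crnn_model")
  rec <- reconstruct_sequence(s$dyn_kspace, full, model)
  ref <- reconstruct_sequence(s$dyn_kspace, full)
  expect_lt(max(abs(rec - ref)) / max(ref), 1e-6)
})

test_that("sampled k-space lines of reconstructed frames are preserved", {
  cfg <- crnn_config(n_iterations = 2, n_filters = 4, window_length = 3)
  g <- 32
  set.seed(35)
  imgs <- lapply(1:3, function(t) matrix(runif(g * g), g))
  mask <- make_central_mask(g, 4)
  k_s <- lapply(imgs, function(m) apply_mask(centered_fft2(m), mask))
  zf <- lapply(k_s, centered_ifft2)
  w <- withr::with_seed(36, needletrack:::init_crnn_weights(cfg))
  fw <- needletrack:::crnn_forward(zf, k_s, mask, w, cfg)
  for (t in 1:3) {
    k_out <- centered_fft2(needletrack:::ch_to_cplx(fw$out[[t]]))
    expect_lt(max(Mod(k_out[mask$retained, ] - k_s[[t]][mask$retained, ])),
              1e-10)
  }
})

test_that("a static sequence reconstructs identically across frames", {
  # every sliding window of a constant-in-time sequence is identical, so
  # each frame's centre-window output must be identical too
  cfg <- crnn_config(n_iterations = 1, n_filters = 4, window_length = 3)
  g <- 32
  set.seed(37)
  img <- matrix(runif(g * g), g)
  mask <- make_central_mask(g, 4)
  k <- centered_fft2(img)
  dyn <- array(rep(k, 5), dim = c(g, g, 1, 5))
  w <- withr::with_seed(38, needletrack:::init_crnn_weights(cfg))
  model <- structure(list(weights = w, cfg = cfg,
                          loss_trace = tibble::tibble(epoch = 1, loss = 1)),
                     class = "crnn_model")
  rec <- reconstruct_sequence(dyn, mask, model)
  for (f in 2:5) expect_equal(rec[, , f], rec[, , 1])
  zf <- reconstruct_sequence(dyn, mask)
  for (f in 2:5) expect_equal(zf[, , f], zf[, , 1])
})

test_that("analytic network gradients match finite differences", {
  cfg <- crnn_config(n_iterations = 2, n_filters = 3, window_length = 3,
                     undersampling_R = 2, ssim_window = 7)
  g <- 16
  set.seed(39)
  mask <- make_central_mask(g, 2)
  targets <- lapply(1:3, function(t) matrix(runif(g * g), g))
  k_s <- lapply(targets, function(m) apply_mask(centered_fft2(m), mask))
  zf <- lapply(k_s, centered_ifft2)
  w <- withr::with_seed(40, needletrack:::init_crnn_weights(cfg))
  lg <- needletrack:::crnn_loss_and_grad(w, cfg, mask, zf, k_s, targets)
  h <- 1e-6
  for (nm in c("W1x", "W1f", "W1b", "W1i", "W2i", "W3x", "W4x", "W5", "b1")) {
    i <- sample(length(w[[nm]]), 1)
    wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
    wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
    num <- (needletrack:::crnn_loss_and_grad(wp, cfg, mask, zf, k_s, targets)$loss -
              needletrack:::crnn_loss_and_grad(wm, cfg, mask, zf, k_s, targets)$loss) /
      (2 * h)
    expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-3)
  }
})

test_that("training is seeded-deterministic and augmentation is active", {
  cfgp <- phantom_config(grid_size = 32, n_coils = 1, n_frames = 3,
                         noise_sigma = 0, rng_seed = 41)
  seqs <- generate_recon_training_set(2, cfgp, seed = 42)
  cfg <- crnn_config(n_iterations = 1, n_filters = 4, window_length = 3,
                     undersampling_R = 4, epochs = 2, rng_seed = 43)
  m1 <- train_recon_model(seqs, cfg)
  m2 <- train_recon_model(seqs, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss_trace, m2$loss_trace)
  cfg_noaug <- cfg
  cfg_noaug$augment <- FALSE
  m3 <- train_recon_model(seqs, cfg_noaug)
  expect_false(identical(m3$loss_trace$loss, m1$loss_trace$loss))
})
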