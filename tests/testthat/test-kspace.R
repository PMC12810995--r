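test_that("centered transforms are orthonormal with DC at the centre", {
  set.seed(1)
  x <- matrix(rnorm(32 * 32), 32) + 1i * matrix(rnorm(32 * 32), 32)
  k <- centered_fft2(x)
  expect_lt(max(Mod(centered_ifft2(k) - x)), 1e-10)
  # Parseval under orthonormal scaling
  expect_lt(abs(sum(Mod(x)^2) - sum(Mod(k)^2)) / sum(Mod(x)^2), 1e-8)
  # constant image concentrates at the 0-based grid_size/2 index
  k1 <- centered_fft2(matrix(1, 16, 16))
  expect_equal(Mod(k1[9, 9]), 16)
  k1[9, 9] <- 0
  expect_lt(max(Mod(k1)), 1e-12)
})

test_that("central masks retain floor(n/R) lines, matching the protocol table", {
  counts <- vapply(c(8, 10, 12, 14, 16, 18, 20, 25),
                   function(R) make_central_mask(256, R)$n_retained,
                   numeric(1))
  expect_equal(counts, c(32, 25, 21, 18, 16, 14, 12, 10))
  expect_equal(make_central_mask(256, 1)$n_retained, 256)
  expect_true(all(make_central_mask(256, 1)$retained))
  # retained block is contiguous and covers the DC line
  m <- make_central_mask(256, 12)
  idx <- which(m$retained)
  expect_equal(idx, seq(min(idx), max(idx)))
  expect_true(m$retained[129]) # 0-based DC index 128
  # odd retained count: extra line on the lower-index side of DC
  expect_equal(sum(m$retained[1:128]), 11)
  expect_equal(sum(m$retained[129:256]), 10)
  expect_error(make_central_mask(256, 300), "retained")
  expect_error(make_central_mask(255, 2))
})

test_that("escalation equals direct construction and strips edges symmetrically", {
  m8 <- make_central_mask(256, 8)
  m16 <- escalate_mask(m8, 16)
  expect_identical(m16$retained, make_central_mask(256, 16)$retained)
  expect_equal(m16$n_retained, 16)
  # 8 lines removed from each edge of the 32-line block
  removed <- which(m8$retained & !m16$retained)
  expect_equal(sum(removed <= 128), 8)
  expect_equal(sum(removed > 128), 8)
  expect_identical(escalate_mask(m8, 8)$retained, m8$retained)
  expect_equal(escalate_mask(m8, 20)$n_retained, 12)
  expect_error(escalate_mask(m16, 8), "escalation")
  # escalate(make(N, R1), R2) == make(N, R2) over a parameter sweep
  for (R1 in c(2, 4, 8)) {
    for (R2 in c(8, 12.5, 16, 25)) {
      if (R2 >= R1) {
        expect_identical(escalate_mask(make_central_mask(64, R1), R2)$retained,
                         make_central_mask(64, R2)$retained)
      }
    }
  }
})

test_that("apply_mask zeroes exactly the unsampled phase lines", {
  set.seed(2)
  k <- matrix(rnorm(64 * 64), 64) + 1i * matrix(rnorm(64 * 64), 64)
  m <- make_central_mask(64, 4)
  km <- apply_mask(k, m)
  expect_identical(km[m$retained, ], k[m$retained, ])
  expect_true(all(km[!m$retained, ] == 0))
  expect_identical(apply_mask(k, make_central_mask(64, 1)), k)
  expect_lte(sum(Mod(km)^2), sum(Mod(k)^2))
  expect_error(apply_mask(k, make_central_mask(32, 2)), "phase lines")
  # retained k-space energy is non-increasing in R
  energies <- vapply(c(1, 2, 4, 8, 16, 32), function(R) {
    sum(Mod(apply_mask(k, make_central_mask(64, R)))^2)
  }, numeric(1))
  expect_true(all(diff(energies) <= 0))
})

test_that("RSS combination and zero-filled reconstruction", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32)
  one <- array(centered_fft2(img), dim = c(32, 32, 1))
  expect_equal(rss_combine(array(img * (1 + 0i), dim = c(32, 32, 1))),
               abs(img))
  expect_equal(rss_combine(array(rep(img, 2), dim = c(32, 32, 2))),
               sqrt(2) * img)
  expect_equal(max(rss_combine(array(0 + 0i, dim = c(8, 8, 3)))), 0)
  # full mask, one coil, non-negative image: exact reproduction
  rec <- zero_fill_reconstruct(one, make_central_mask(32, 1))
  expect_lt(max(abs(rec - img)), 1e-8)
  # undersampled: error > 0 and blur confined to the phase (row) axis
  sharp <- matrix(0, 64, 64)
  sharp[20:44, 20:44] <- 1
  rec8 <- zero_fill_reconstruct(centered_fft2(sharp), make_central_mask(64, 8))
  expect_gt(max(abs(rec8 - sharp)), 0.1)
  # energy leaked outside the square concentrates along the phase (row) axis
  es <- c(row = sum(rec8[c(1:15, 49:64), 20:44]^2),
          col = sum(rec8[20:44, c(1:15, 49:64)]^2))
  expect_gt(es["row"], 100 * max(es["col"], 1e-12))
})

test_that("intensity scaling is global over the sequence", {
  frames <- list(matrix(c(0, 1, 2, 3), 2), matrix(c(4, 5, 6, 8), 2))
  sc <- scale_intensities(frames)
  expect_equal(min(sc[[1]]), 0)
  expect_equal(max(sc[[2]]), 1)
  expect_equal(sc[[1]][2, 1], 1 / 8)
  # scale invariance
  expect_equal(scale_intensities(lapply(frames, `*`, 10)), sc)
  # already [0, 1] with attained bounds: unchanged
  u <- list(matrix(c(0, 0.5, 1, 0.25), 2))
  expect_equal(scale_intensities(u), u)
  # constant sequence maps to zeros
  expect_equal(scale_intensities(list(matrix(7, 2, 2)))[[1]], matrix(0, 2, 2))
})

test_that("protocol arithmetic reproduces the published acquisition numbers", {
  expect_equal(effective_undersampling(320, 68), 4.7)
  expect_equal(effective_undersampling(256, 32), 8.0)
  expect_equal(effective_undersampling(128, 128), 1.0)
  expect_equal(scan_time(4.56, 320, 5), 7.30)
  expect_equal(scan_time(4.68, 68, 60), 19.09)
  expect_equal(scan_time(4.68, 68, 1), 0.32)
  expect_equal(scan_time(4.56, 320, 0), 0)
})

test_that("sampling masks round-trip through JSON bit-exactly", {
  m <- make_central_mask(256, 12)
  path <- withr::local_tempfile(fileext = ".json")
  mask_to_json(m, path)
  m2 <- mask_from_json(path)
  expect_identical(m2$retained, m$retained)
  expect_equal(m2$n_retained, m$n_retained)
  expect_equal(m2$nominal_R, m$nominal_R)
})
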