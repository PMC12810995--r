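# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: explicit loops, closed forms, and quadratic
# eigen-solutions instead of eigen()/cov()/vectorized kernels.

# brute-force principal-axis tip: explicit sums and the closed-form
# eigendecomposition of a symmetric 2x2 matrix
oracle_pca_tip <- function(mask, spacing, image_center = NULL) {
  if (is.null(image_center)) {
    image_center <- c(nrow(mask), ncol(mask)) * spacing / 2
  }
  pts <- NULL
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) pts <- rbind(pts, (c(i, j) - 0.5) * spacing)
    }
  }
  if (is.null(pts) || nrow(pts) < 2) return(NULL)
  n <- nrow(pts)
  ctr <- c(sum(pts[, 1]), sum(pts[, 2])) / n
  sxx <- sum((pts[, 1] - ctr[1])^2) / (n - 1)
  syy <- sum((pts[, 2] - ctr[2])^2) / (n - 1)
  sxy <- sum((pts[, 1] - ctr[1]) * (pts[, 2] - ctr[2])) / (n - 1)
  # eigenvalues of [[sxx, sxy], [sxy, syy]] by the quadratic formula
  tr <- sxx + syy
  disc <- sqrt(max(0, (sxx - syy)^2 + 4 * sxy^2))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (l1 - l2 <= 1e-9) return(NULL)
  v <- if (abs(sxy) > 1e-300) c(l1 - syy, sxy) else if (sxx >= syy) c(1, 0) else c(0, 1)
  v <- v / sqrt(sum(v^2))
  proj <- (pts[, 1] - ctr[1]) * v[1] + (pts[, 2] - ctr[2]) * v[2]
  e1 <- ctr + min(proj) * v
  e2 <- ctr + max(proj) * v
  d1 <- sum((e1 - image_center)^2)
  d2 <- sum((e2 - image_center)^2)
  if (abs(d1 - d2) <= 1e-9 * max(1, d1)) {
    # tie: smaller row, then column, coordinate (sign-invariant)
    if (e1[1] < e2[1] || (e1[1] == e2[1] && e1[2] <= e2[2])) e1 else e2
  } else if (d1 < d2) {
    e1
  } else {
    e2
  }
}

# Wilson score interval evaluated directly from the closed form
oracle_wilson <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n))
}

# small noiseless single-coil sample shared by pipeline tests
tiny_sample <- function(grid = 64, frames = 10, coils = 1, noise = 0,
                        seed = 11) {
  generate_sample(phantom_config(grid_size = grid, n_coils = coils,
                                 n_frames = frames, noise_sigma = noise,
                                 rng_seed = seed))
}

# random mask generator for the pca oracle suite: mixes elongated rods,
# scatter clouds, and small blobs, capped at max_px pixels
random_mask <- function(grid = 24, max_px = 200) {
  m <- matrix(FALSE, grid, grid)
  kind <- sample(3, 1)
  if (kind == 1) { # rod at arbitrary angle
    ang <- runif(1, 0, pi)
    len <- runif(1, grid / 3, grid - 2)
    ctr <- runif(2, grid * 0.3, grid * 0.7)
    b <- ctr - len / 2 * c(cos(ang), sin(ang))
    t <- ctr + len / 2 * c(cos(ang), sin(ang))
    suppressWarnings(
      m <- rasterize_guide_mask(b, t, runif(1, 0.4, 2), 1, grid)
    )
  } else if (kind == 2) { # anisotropic gaussian scatter
    n <- sample(5:60, 1)
    pts <- cbind(round(rnorm(n, grid / 2, grid / 5)),
                 round(rnorm(n, grid / 2, grid / 10)))
    pts <- pts[pts[, 1] >= 1 & pts[, 1] <= grid &
                 pts[, 2] >= 1 & pts[, 2] <= grid, , drop = FALSE]
    m[pts] <- TRUE
  } else { # a few random pixels
    n <- sample(2:10, 1)
    m[sample(grid * grid, n)] <- TRUE
  }
  if (sum(m) > max_px) {
    on <- which(m)
    m[on[-seq_len(max_px)]] <- FALSE
  }
  m
}
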