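#' Structural similarity index (SSIM) between two images
#'
#' Windowed SSIM with the standard Gaussian window (11 x 11, sigma 1.5) and
#' stability constants `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2` for dynamic range
#' `L`. Local statistics are computed over the valid interior (no padded
#' windows), and the score is their mean; `ssim(x, x)` is exactly 1 and the
#' measure is symmetric in its arguments.
#'
#' @param a,b Numeric matrices of identical dimension with intensities in
#'   `[0, dynamic_range]`.
#' @param window_size Odd window size; both image dimensions must be at
#'   least this large. Default 11.
#' @param sigma Gaussian window standard deviation in pixels. Default 1.5.
#' @param K1,K2 Stability constants. Defaults 0.01 and 0.03.
#' @param dynamic_range Intensity range `L`. Default 1.
#' @param return_map Return the per-window SSIM map instead of its mean.
#' @return Mean SSIM in `[-1, 1]`, or the valid-region SSIM map.
#' @export
ssim <- function(a, b, window_size = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 dynamic_range = 1, return_map = FALSE) {
  st <- ssim_stats(a, b, window_size, sigma, K1, K2, dynamic_range)
  if (return_map) st$S else mean(st$S)
}

gaussian_window <- function(window_size, sigma) {
  half <- (window_size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# correlation with the window, cropped to the valid interior
win_filter <- function(x, wvec, K) {
  pad <- (K - 1) / 2
  dim(x) <- c(dim(x), 1L)
  y <- nt_conv2d_fwd(x, matrix(wvec, ncol = 1), 0, K)[, , 1]
  y[(pad + 1):(nrow(y) - pad), (pad + 1):(ncol(y) - pad)]
}

ssim_stats <- function(a, b, window_size, sigma, K1, K2, dynamic_range) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)),
            window_size %% 2 == 1, min(dim(a)) >= window_size)
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  wvec <- as.vector(gaussian_window(window_size, sigma))
  mu_a <- win_filter(a, wvec, window_size)
  mu_b <- win_filter(b, wvec, window_size)
  s_aa <- win_filter(a * a, wvec, window_size) - mu_a^2
  s_bb <- win_filter(b * b, wvec, window_size) - mu_b^2
  s_ab <- win_filter(a * b, wvec, window_size) - mu_a * mu_b
  A1 <- 2 * mu_a * mu_b + C1
  A2 <- 2 * s_ab + C2
  B1 <- mu_a^2 + mu_b^2 + C1
  B2 <- s_aa + s_bb + C2
  list(S = (A1 * A2) / (B1 * B2), mu_a = mu_a, mu_b = mu_b,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, wvec = wvec, K = window_size)
}

# adjoint of win_filter: embed a valid-region map and scatter back through
# the window
win_filter_adj <- function(m, wvec, K, full_dim) {
  pad <- (K - 1) / 2
  g <- matrix(0, full_dim[1], full_dim[2])
  g[(pad + 1):(full_dim[1] - pad), (pad + 1):(full_dim[2] - pad)] <- m
  dim(g) <- c(full_dim, 1L)
  x0 <- array(0, dim = c(full_dim, 1L))
  nt_conv2d_bwd(x0, matrix(wvec, ncol = 1), g, K)$gx[, , 1]
}

# gradient of mean SSIM with respect to the first image
ssim_grad <- function(a, b, window_size = 11, sigma = 1.5, K1 = 0.01,
                      K2 = 0.03, dynamic_range = 1) {
  st <- ssim_stats(a, b, window_size, sigma, K1, K2, dynamic_range)
  S <- st$S
  d_mu <- 2 * st$mu_b * st$A2 / (st$B1 * st$B2) - 2 * st$mu_a * S / st$B1
  d_va <- -S / st$B2
  d_cov <- 2 * st$A1 / (st$B1 * st$B2)
  n <- length(S)
  fd <- dim(a)
  (win_filter_adj(d_mu - 2 * st$mu_a * d_va - st$mu_b * d_cov,
                  st$wvec, st$K, fd) +
      2 * a * win_filter_adj(d_va, st$wvec, st$K, fd) +
      b * win_filter_adj(d_cov, st$wvec, st$K, fd)) / n
}
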