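#' Configuration for the recurrent reconstruction network
#'
#' The network unrolls an iterative reconstruction: each of `n_iterations`
#' passes applies five convolutional units to every frame of a short temporal
#' window — one bidirectional unit recurrent over both time and iterations,
#' three units recurrent over iterations only, and one plain convolutional
#' unit — followed by a residual connection and a hard data-consistency step
#' that re-imposes the sampled k-space lines exactly. Training minimizes
#' `1 - SSIM` between the output magnitude and the fully sampled target.
#' `crnn_config()` gives a desk-scale model suitable for CPU experiments;
#' `crnn_config_full()` is the full-scale preset (10 iterations, 128
#' filters).
#'
#' @param n_iterations Unrolled iterations. Desk default 2.
#' @param n_filters Convolution filters per unit. Desk default 16.
#' @param kernel_size Odd convolution kernel size. Default 3.
#' @param window_length Odd temporal window length. Default 5.
#' @param undersampling_R Acceleration at which undersampling is synthesized
#'   during training. Default 8.
#' @param epochs,learning_rate,rician_sigma,augment Training schedule: Adam
#'   learning rate, number of epochs, k-space noise level of the Rician
#'   augmentation, and whether flip/rotation/noise augmentation is active.
#' @param ssim_window SSIM window size used by the loss. Default 11.
#' @param rng_seed Integer seed controlling initialization, data order and
#'   augmentation.
#' @return An object of class `crnn_config`.
#' @export
crnn_config <- function(n_iterations = 2, n_filters = 16, kernel_size = 3,
                        window_length = 5, undersampling_R = 8, epochs = 40,
                        learning_rate = 1e-3, rician_sigma = 0.02,
                        augment = TRUE, ssim_window = 11, rng_seed = 1L) {
  stopifnot(n_iterations >= 1, n_filters >= 1, kernel_size %% 2 == 1,
            window_length %% 2 == 1, undersampling_R >= 1, epochs >= 1,
            learning_rate > 0, ssim_window %% 2 == 1)
  structure(
    list(n_iterations = as.integer(n_iterations),
         n_filters = as.integer(n_filters),
         kernel_size = as.integer(kernel_size),
         window_length = as.integer(window_length),
         undersampling_R = undersampling_R, epochs = as.integer(epochs),
         learning_rate = learning_rate, rician_sigma = rician_sigma,
         augment = isTRUE(augment), ssim_window = as.integer(ssim_window),
         rng_seed = as.integer(rng_seed)),
    class = "crnn_config"
  )
}

#' @rdname crnn_config
#' @param ... Overrides passed on to `crnn_config()`.
#' @export
crnn_config_full <- function(...) {
  crnn_config(n_iterations = 10, n_filters = 128, ...)
}

#' Hard data consistency
#'
#' Overwrites the predicted k-space with the measured values on every
#' sampled (retained) phase-encoding line, leaving the prediction untouched
#' elsewhere. This is the noiseless limit of a data-consistency layer and
#' guarantees that reconstructions agree with the acquisition exactly where
#' data exist.
#'
#' @param pred_kspace,sampled_kspace Complex matrices of identical shape.
#' @param mask A [make_central_mask()] `sampling_mask`.
#' @return Complex matrix equal to `sampled_kspace` on retained lines and
#'   `pred_kspace` elsewhere.
#' @export
data_consistency <- function(pred_kspace, sampled_kspace, mask) {
  stopifnot(all(dim(pred_kspace) == dim(sampled_kspace)),
            inherits(mask, "sampling_mask"),
            nrow(pred_kspace) == mask$n_phase)
  out <- pred_kspace
  out[mask$retained, ] <- sampled_kspace[mask$retained, ]
  out
}

# image-domain data consistency on a two-channel real array
dc_image <- function(x_ch, k_sampled, mask) {
  zk <- centered_fft2(ch_to_cplx(x_ch))
  zk[mask$retained, ] <- k_sampled[mask$retained, ]
  cplx_to_ch(centered_ifft2(zk))
}

# adjoint of dc_image w.r.t. its image input: project onto unsampled lines
dc_project_unsampled <- function(g_ch, mask) {
  zk <- centered_fft2(ch_to_cplx(g_ch))
  zk[mask$retained, ] <- 0
  cplx_to_ch(centered_ifft2(zk))
}

init_crnn_weights <- function(cfg, zero = FALSE) {
  K <- cfg$kernel_size
  nf <- cfg$n_filters
  mk <- function(cin, cout) {
    if (zero) matrix(0, K * K * cin, cout) else init_conv_w(K, cin, cout)
  }
  w <- list(
    W1x = mk(2, nf), W1f = mk(nf, nf), W1b = mk(nf, nf), W1i = mk(nf, nf),
    b1 = rep(0, nf),
    W2x = mk(nf, nf), W2i = mk(nf, nf), b2 = rep(0, nf),
    W3x = mk(nf, nf), W3i = mk(nf, nf), b3 = rep(0, nf),
    W4x = mk(nf, nf), W4i = mk(nf, nf), b4 = rep(0, nf),
    W5 = mk(nf, 2), b5 = rep(0, 2)
  )
  w
}

# Forward pass over one temporal window. zf / k_sampled: lists (length T) of
# complex matrices; returns per-frame two-channel outputs and, optionally,
# the activation cache needed for backpropagation.
crnn_forward <- function(zf, k_sampled, mask, w, cfg, keep_cache = FALSE) {
  T_ <- length(zf)
  H <- nrow(zf[[1]])
  Wd <- ncol(zf[[1]])
  K <- cfg$kernel_size
  nf <- cfg$n_filters
  z4 <- function() lapply(seq_len(T_), function(t) zeros_like_hw(H, Wd, nf))
  x <- lapply(zf, cplx_to_ch)
  hprev <- list(z4(), z4(), z4(), z4())
  cache <- vector("list", cfg$n_iterations)
  zb <- rep(0, nf)
  for (i in seq_len(cfg$n_iterations)) {
    a <- lapply(seq_len(T_), function(t) {
      conv_fwd(x[[t]], w$W1x, w$b1, K) +
        conv_fwd(hprev[[1]][[t]], w$W1i, zb, K)
    })
    hf <- vector("list", T_)
    for (t in seq_len(T_)) {
      pre <- a[[t]]
      if (t > 1) pre <- pre + conv_fwd(hf[[t - 1]], w$W1f, zb, K)
      hf[[t]] <- relu(pre)
    }
    hb <- vector("list", T_)
    for (t in rev(seq_len(T_))) {
      pre <- a[[t]]
      if (t < T_) pre <- pre + conv_fwd(hb[[t + 1]], w$W1b, zb, K)
      hb[[t]] <- relu(pre)
    }
    h1 <- Map(`+`, hf, hb)
    h2 <- lapply(seq_len(T_), function(t) {
      relu(conv_fwd(h1[[t]], w$W2x, w$b2, K) +
             conv_fwd(hprev[[2]][[t]], w$W2i, zb, K))
    })
    h3 <- lapply(seq_len(T_), function(t) {
      relu(conv_fwd(h2[[t]], w$W3x, w$b3, K) +
             conv_fwd(hprev[[3]][[t]], w$W3i, zb, K))
    })
    h4 <- lapply(seq_len(T_), function(t) {
      relu(conv_fwd(h3[[t]], w$W4x, w$b4, K) +
             conv_fwd(hprev[[4]][[t]], w$W4i, zb, K))
    })
    x_new <- vector("list", T_)
    for (t in seq_len(T_)) {
      o <- conv_fwd(h4[[t]], w$W5, w$b5, K)
      x_new[[t]] <- dc_image(x[[t]] + o, k_sampled[[t]], mask)
    }
    if (keep_cache) {
      cache[[i]] <- list(x_in = x, hf = hf, hb = hb, h1 = h1, h2 = h2,
                         h3 = h3, h4 = h4, hprev = hprev)
    }
    hprev <- list(h1, h2, h3, h4)
    x <- x_new
  }
  list(out = x, cache = if (keep_cache) cache else NULL)
}

# Backpropagation through the unrolled network. g_out: list (length T) of
# two-channel gradients w.r.t. the final per-frame image. Returns weight
# gradients with the same names/shapes as the weights.
crnn_backward <- function(w, cfg, mask, cache, g_out) {
  T_ <- length(g_out)
  K <- cfg$kernel_size
  nf <- cfg$n_filters
  H <- dim(g_out[[1]])[1]
  Wd <- dim(g_out[[1]])[2]
  gr <- lapply(w, function(p) p * 0)
  z4 <- function() lapply(seq_len(T_), function(t) zeros_like_hw(H, Wd, nf))
  g_x <- g_out
  g_h <- list(z4(), z4(), z4(), z4())
  acc <- function(nmW, nmB, bw) {
    gr[[nmW]] <<- gr[[nmW]] + bw$gw
    if (!is.null(nmB)) gr[[nmB]] <<- gr[[nmB]] + bw$gb
  }
  for (i in rev(seq_len(cfg$n_iterations))) {
    ch <- cache[[i]]
    new_g_h <- list(z4(), z4(), z4(), z4())
    g_xprev <- vector("list", T_)
    g_a <- vector("list", T_)
    # per-frame backward through DC, residual, unit 5, units 4..2
    g_h1 <- vector("list", T_)
    for (t in seq_len(T_)) {
      g_xt <- dc_project_unsampled(g_x[[t]], mask)
      g_xprev[[t]] <- g_xt
      bw5 <- conv_bwd(ch$h4[[t]], w$W5, g_xt, K)
      acc("W5", "b5", bw5)
      g_pre4 <- (bw5$gx + g_h[[4]][[t]]) * (ch$h4[[t]] > 0)
      bw4x <- conv_bwd(ch$h3[[t]], w$W4x, g_pre4, K)
      acc("W4x", "b4", bw4x)
      if (i > 1) {
        bw4i <- conv_bwd(ch$hprev[[4]][[t]], w$W4i, g_pre4, K)
        acc("W4i", NULL, bw4i)
        new_g_h[[4]][[t]] <- bw4i$gx
      }
      g_pre3 <- (bw4x$gx + g_h[[3]][[t]]) * (ch$h3[[t]] > 0)
      bw3x <- conv_bwd(ch$h2[[t]], w$W3x, g_pre3, K)
      acc("W3x", "b3", bw3x)
      if (i > 1) {
        bw3i <- conv_bwd(ch$hprev[[3]][[t]], w$W3i, g_pre3, K)
        acc("W3i", NULL, bw3i)
        new_g_h[[3]][[t]] <- bw3i$gx
      }
      g_pre2 <- (bw3x$gx + g_h[[2]][[t]]) * (ch$h2[[t]] > 0)
      bw2x <- conv_bwd(ch$h1[[t]], w$W2x, g_pre2, K)
      acc("W2x", "b2", bw2x)
      if (i > 1) {
        bw2i <- conv_bwd(ch$hprev[[2]][[t]], w$W2i, g_pre2, K)
        acc("W2i", NULL, bw2i)
        new_g_h[[2]][[t]] <- bw2i$gx
      }
      g_h1[[t]] <- bw2x$gx + g_h[[1]][[t]]
    }
    # bidirectional unit: backprop through time for both directions
    g_hf <- g_h1
    for (t in rev(seq_len(T_))) {
      g_pref <- g_hf[[t]] * (ch$hf[[t]] > 0)
      g_a[[t]] <- g_pref
      if (t > 1) {
        bwf <- conv_bwd(ch$hf[[t - 1]], w$W1f, g_pref, K)
        acc("W1f", NULL, bwf)
        g_hf[[t - 1]] <- g_hf[[t - 1]] + bwf$gx
      }
    }
    g_hb <- g_h1
    for (t in seq_len(T_)) {
      g_preb <- g_hb[[t]] * (ch$hb[[t]] > 0)
      g_a[[t]] <- g_a[[t]] + g_preb
      if (t < T_) {
        bwb <- conv_bwd(ch$hb[[t + 1]], w$W1b, g_preb, K)
        acc("W1b", NULL, bwb)
        g_hb[[t + 1]] <- g_hb[[t + 1]] + bwb$gx
      }
    }
    for (t in seq_len(T_)) {
      bw1x <- conv_bwd(ch$x_in[[t]], w$W1x, g_a[[t]], K)
      acc("W1x", "b1", bw1x)
      g_xprev[[t]] <- g_xprev[[t]] + bw1x$gx
      if (i > 1) {
        bw1i <- conv_bwd(ch$hprev[[1]][[t]], w$W1i, g_a[[t]], K)
        acc("W1i", NULL, bw1i)
        new_g_h[[1]][[t]] <- bw1i$gx
      }
    }
    g_x <- g_xprev
    g_h <- new_g_h
  }
  gr
}

# loss = mean over frames of (1 - SSIM(|out|, target)); returns loss and
# weight gradients for one window
crnn_loss_and_grad <- function(w, cfg, mask, zf, k_sampled, targets) {
  fw <- crnn_forward(zf, k_sampled, mask, w, cfg, keep_cache = TRUE)
  T_ <- length(zf)
  eps <- 1e-8
  loss <- 0
  g_out <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- ch_to_cplx(fw$out[[t]])
    m <- Mod(z)
    loss <- loss + (1 - ssim(m, targets[[t]], window_size = cfg$ssim_window))
    gm <- -ssim_grad(m, targets[[t]], window_size = cfg$ssim_window) / T_
    denom <- pmax(m, eps)
    g <- array(0, dim = c(dim(m), 2L))
    g[, , 1] <- gm * Re(z) / denom
    g[, , 2] <- gm * Im(z) / denom
    g_out[[t]] <- g
  }
  list(loss = loss / T_,
       grads = crnn_backward(w, cfg, mask, fw$cache, g_out))
}

# deterministic per-sequence augmentation: flips, 90-degree rotations
rot90m <- function(m, k) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  m
}

augment_sequence <- function(frames) {
  fh <- stats::runif(1) < 0.5
  fv <- stats::runif(1) < 0.5
  k <- sample(0:3, 1)
  lapply(frames, function(m) {
    if (fh) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (fv) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    rot90m(m, k)
  })
}

#' Train the recurrent reconstruction network
#'
#' Trains on fully sampled image sequences; undersampling is synthesized on
#' the fly by masking the k-space of each (optionally augmented) frame to
#' the central lines at `cfg$undersampling_R`. Augmentation applies random
#' horizontal/vertical flips, rotations by multiples of 90 degrees, and
#' additional Rician noise (complex Gaussian noise added in k-space to the
#' network input only). One Adam step is taken per sequence; training is
#' deterministic given `cfg$rng_seed`.
#'
#' @param sequences List of training sequences, each a list of real-valued
#'   `[0, 1]` frame matrices of length `cfg$window_length` (longer sequences
#'   are windowed).
#' @param cfg A [crnn_config()].
#' @return An object of class `crnn_model`: weights, the config, and a
#'   `loss_trace` tibble (`epoch`, `loss`).
#' @export
train_recon_model <- function(sequences, cfg) {
  stopifnot(inherits(cfg, "crnn_config"), length(sequences) >= 1)
  g <- nrow(sequences[[1]][[1]])
  mask <- make_central_mask(g, cfg$undersampling_R)
  wl <- cfg$window_length
  trace <- numeric(cfg$epochs)
  withr::with_seed(cfg$rng_seed, {
    w <- init_crnn_weights(cfg)
    opt <- adam_init(w)
    for (ep in seq_len(cfg$epochs)) {
      tot <- 0
      nwin <- 0
      for (s in sample(length(sequences))) {
        frames <- sequences[[s]]
        if (cfg$augment) frames <- augment_sequence(frames)
        # window long sequences; most corpora are exactly one window
        starts <- seq(1, max(1, length(frames) - wl + 1), by = wl)
        for (st in starts) {
          fr <- frames[st:min(length(frames), st + wl - 1)]
          k_clean <- lapply(fr, centered_fft2)
          k_in <- lapply(k_clean, function(k) {
            if (cfg$augment && cfg$rician_sigma > 0) {
              k + cfg$rician_sigma *
                (matrix(stats::rnorm(length(k)), nrow(k)) +
                   1i * matrix(stats::rnorm(length(k)), nrow(k)))
            } else k
          })
          k_samp <- lapply(k_in, apply_mask, mask = mask)
          zf <- lapply(k_samp, centered_ifft2)
          lg <- crnn_loss_and_grad(w, cfg, mask, zf, k_samp, fr)
          if (!is.finite(lg$loss)) {
            stop("reconstruction training diverged (non-finite loss) at ",
                 "epoch ", ep)
          }
          upd <- adam_step(w, lg$grads, opt, cfg$learning_rate)
          w <- upd$params
          opt <- upd$state
          tot <- tot + lg$loss
          nwin <- nwin + 1
        }
      }
      trace[ep] <- tot / nwin
    }
  })
  structure(
    list(weights = w, cfg = cfg,
         loss_trace = tibble::tibble(epoch = seq_len(cfg$epochs),
                                     loss = trace)),
    class = "crnn_model"
  )
}

#' @export
print.crnn_model <- function(x, ...) {
  cat("<crnn_model> ", x$cfg$n_iterations, " iterations, ",
      x$cfg$n_filters, " filters, trained ", nrow(x$loss_trace),
      " epochs (final loss ",
      signif(utils::tail(x$loss_trace$loss, 1), 4), ")\n", sep = "")
  invisible(x)
}

#' Reconstruct a dynamic sequence with a sliding temporal window
#'
#' Each output frame is the centre-frame result of running the network on
#' the window centred on it (replicate padding at the sequence edges). With
#' `model = NULL` the zero-filled reconstruction is returned instead. For
#' multi-coil input the network is applied coil by coil with shared weights
#' and per-coil data consistency, and outputs are combined by root sum of
#' squares; the final data-consistency step guarantees that each coil's
#' k-space matches the sampled lines exactly.
#'
#' @param dyn_kspace Complex array `N x N x n_coils x n_frames` of fully
#'   sampled or acquired k-space frames.
#' @param mask A `sampling_mask` applied to every frame.
#' @param model A trained [train_recon_model()] result, or `NULL`.
#' @return Magnitude array `N x N x n_frames`.
#' @export
reconstruct_sequence <- function(dyn_kspace, mask, model = NULL) {
  stopifnot(length(dim(dyn_kspace)) == 4)
  d <- dim(dyn_kspace)
  n_frames <- d[4]
  n_coils <- d[3]
  out <- array(0, dim = c(d[1], d[2], n_frames))
  if (is.null(model)) {
    for (f in seq_len(n_frames)) {
      ks <- dyn_kspace[, , , f]
      if (n_coils == 1) dim(ks) <- d[1:2]
      out[, , f] <- zero_fill_reconstruct(ks, mask)
    }
    return(out)
  }
  stopifnot(inherits(model, "crnn_model"))
  cfg <- model$cfg
  half <- (cfg$window_length - 1) / 2
  for (f in seq_len(n_frames)) {
    idx <- pmin(pmax(seq(f - half, f + half), 1), n_frames)
    coil_out <- array(0 + 0i, dim = c(d[1], d[2], n_coils))
    for (cc in seq_len(n_coils)) {
      k_samp <- lapply(idx, function(j) {
        apply_mask(dyn_kspace[, , cc, j], mask)
      })
      zf <- lapply(k_samp, centered_ifft2)
      fw <- crnn_forward(zf, k_samp, mask, model$weights, cfg)
      coil_out[, , cc] <- ch_to_cplx(fw$out[[half + 1]])
    }
    out[, , f] <- rss_combine(coil_out)
  }
  out
}
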