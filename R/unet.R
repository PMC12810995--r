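#' Configuration for the needle-guide segmenter
#'
#' A small fixed-architecture 2D U-Net (encoder/decoder with skip
#' connections, two 3x3 convolutions per level, 2x2 max pooling, nearest
#' upsampling) trained with the sum of binary cross-entropy and soft Dice
#' loss. The foreground probability map is thresholded at `threshold`;
#' optionally only the largest connected component is kept.
#'
#' @param depth Number of pooling levels (`>= 2`). Default 2.
#' @param base_filters Filters at the first level; doubled per level.
#'   Default 8.
#' @param epochs,learning_rate Adam training schedule.
#' @param val_fraction Fraction of subjects held out by [split_dataset()].
#'   Default 0.2.
#' @param threshold Foreground probability threshold. Default 0.5.
#' @param keep_largest_component Keep only the largest connected foreground
#'   component at inference (off by default).
#' @param rng_seed Integer seed.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(depth = 2, base_filters = 8, epochs = 30,
                       learning_rate = 1e-3, val_fraction = 0.2,
                       threshold = 0.5, keep_largest_component = FALSE,
                       rng_seed = 1L) {
  stopifnot(depth >= 2, base_filters >= 1, epochs >= 1, learning_rate > 0,
            val_fraction > 0, val_fraction < 1, threshold > 0, threshold < 1)
  structure(
    list(depth = as.integer(depth), base_filters = as.integer(base_filters),
         epochs = as.integer(epochs), learning_rate = learning_rate,
         val_fraction = val_fraction, threshold = threshold,
         keep_largest_component = isTRUE(keep_largest_component),
         rng_seed = as.integer(rng_seed)),
    class = "seg_config"
  )
}

#' Patient-level train/validation split
#'
#' Splits a data frame of scans into disjoint, exhaustive train and
#' validation sets at the level of (synthetic) subjects: every row sharing a
#' subject id lands on the same side. The split is deterministic given the
#' seed.
#'
#' @param data Data frame with a subject identifier column.
#' @param fraction Fraction of subjects assigned to training. Default 0.8.
#' @param seed Integer seed.
#' @param subject_col Name of the subject column. Default `"subject"`.
#' @return Named list of two tibbles, `train` and `val`.
#' @export
split_dataset <- function(data, fraction = 0.8, seed = 1L,
                          subject_col = "subject") {
  stopifnot(is.data.frame(data), subject_col %in% names(data),
            fraction > 0, fraction < 1)
  subjects <- unique(data[[subject_col]])
  if (length(subjects) < 2) {
    stop("need at least two subjects to split")
  }
  n_train <- max(1, min(length(subjects) - 1,
                        round(fraction * length(subjects))))
  withr::with_seed(seed, {
    train_subj <- sample(subjects, n_train)
  })
  is_train <- data[[subject_col]] %in% train_subj
  list(train = tibble::as_tibble(data[is_train, , drop = FALSE]),
       val = tibble::as_tibble(data[!is_train, , drop = FALSE]))
}

unet_channels <- function(cfg) {
  enc <- cfg$base_filters * 2^(seq_len(cfg$depth) - 1)
  list(enc = enc, bottleneck = cfg$base_filters * 2^cfg$depth)
}

init_unet_weights <- function(cfg) {
  chs <- unet_channels(cfg)
  K <- 3
  w <- list()
  cin <- 1
  for (l in seq_len(cfg$depth)) {
    co <- chs$enc[l]
    w[[paste0("enc", l, "_w1")]] <- init_conv_w(K, cin, co)
    w[[paste0("enc", l, "_b1")]] <- rep(0, co)
    w[[paste0("enc", l, "_w2")]] <- init_conv_w(K, co, co)
    w[[paste0("enc", l, "_b2")]] <- rep(0, co)
    cin <- co
  }
  w$bot_w1 <- init_conv_w(K, cin, chs$bottleneck)
  w$bot_b1 <- rep(0, chs$bottleneck)
  w$bot_w2 <- init_conv_w(K, chs$bottleneck, chs$bottleneck)
  w$bot_b2 <- rep(0, chs$bottleneck)
  cup <- chs$bottleneck
  for (l in rev(seq_len(cfg$depth))) {
    co <- chs$enc[l]
    w[[paste0("dec", l, "_w1")]] <- init_conv_w(K, cup + co, co)
    w[[paste0("dec", l, "_b1")]] <- rep(0, co)
    w[[paste0("dec", l, "_w2")]] <- init_conv_w(K, co, co)
    w[[paste0("dec", l, "_b2")]] <- rep(0, co)
    cup <- co
  }
  w$out_w <- init_conv_w(K, cup, 1)
  w$out_b <- 0
  w
}

upsample2 <- function(x) {
  ri <- rep(seq_len(dim(x)[1]), each = 2)
  ci <- rep(seq_len(dim(x)[2]), each = 2)
  x[ri, ci, , drop = FALSE]
}

upsample2_bwd <- function(gy) {
  H2 <- dim(gy)[1]
  W2 <- dim(gy)[2]
  g <- gy[seq(1, H2, 2), , , drop = FALSE] + gy[seq(2, H2, 2), , , drop = FALSE]
  g[, seq(1, W2, 2), , drop = FALSE] + g[, seq(2, W2, 2), , drop = FALSE]
}

unet_forward <- function(x, w, cfg, keep_cache = FALSE) {
  K <- 3
  cache <- list(enc = vector("list", cfg$depth),
                pool = vector("list", cfg$depth),
                dec = vector("list", cfg$depth))
  cur <- as_chw(x)
  for (l in seq_len(cfg$depth)) {
    a1 <- relu(conv_fwd(cur, w[[paste0("enc", l, "_w1")]],
                        w[[paste0("enc", l, "_b1")]], K))
    a2 <- relu(conv_fwd(a1, w[[paste0("enc", l, "_w2")]],
                        w[[paste0("enc", l, "_b2")]], K))
    pl <- nt_maxpool2_fwd(a2)
    cache$enc[[l]] <- list(input = cur, a1 = a1, a2 = a2)
    cache$pool[[l]] <- pl$idx
    cur <- pl$y
  }
  b1 <- relu(conv_fwd(cur, w$bot_w1, w$bot_b1, K))
  b2 <- relu(conv_fwd(b1, w$bot_w2, w$bot_b2, K))
  cache$bot <- list(input = cur, a1 = b1, a2 = b2)
  cur <- b2
  for (l in rev(seq_len(cfg$depth))) {
    up <- upsample2(cur)
    skip <- cache$enc[[l]]$a2
    cat_in <- array(c(up, skip), dim = c(dim(up)[1], dim(up)[2],
                                         dim(up)[3] + dim(skip)[3]))
    d1 <- relu(conv_fwd(cat_in, w[[paste0("dec", l, "_w1")]],
                        w[[paste0("dec", l, "_b1")]], K))
    d2 <- relu(conv_fwd(d1, w[[paste0("dec", l, "_w2")]],
                        w[[paste0("dec", l, "_b2")]], K))
    cache$dec[[l]] <- list(cat_in = cat_in, a1 = d1, a2 = d2,
                           n_up = dim(up)[3])
    cur <- d2
  }
  logits <- conv_fwd(cur, w$out_w, w$out_b, K)[, , 1]
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

unet_backward <- function(w, cfg, cache, g_logits) {
  K <- 3
  gr <- lapply(w, function(p) p * 0)
  acc <- function(nm, bnm, bw) {
    gr[[nm]] <<- gr[[nm]] + bw$gw
    gr[[bnm]] <<- gr[[bnm]] + bw$gb
  }
  g <- as_chw(g_logits)
  bw <- conv_bwd(cache$dec[[1]]$a2, w$out_w, g, K)
  acc("out_w", "out_b", bw)
  g <- bw$gx
  for (l in seq_len(cfg$depth)) {
    dc <- cache$dec[[l]]
    g2 <- g * (dc$a2 > 0)
    bw2 <- conv_bwd(dc$a1, w[[paste0("dec", l, "_w2")]], g2, K)
    acc(paste0("dec", l, "_w2"), paste0("dec", l, "_b2"), bw2)
    g1 <- bw2$gx * (dc$a1 > 0)
    bw1 <- conv_bwd(dc$cat_in, w[[paste0("dec", l, "_w1")]], g1, K)
    acc(paste0("dec", l, "_w1"), paste0("dec", l, "_b1"), bw1)
    n_up <- dc$n_up
    g_up <- bw1$gx[, , seq_len(n_up), drop = FALSE]
    g_skip <- bw1$gx[, , -seq_len(n_up), drop = FALSE]
    # skip-connection gradient joins the encoder backward pass later;
    # the upsample-path gradient continues to the next (deeper) stage,
    # ending at the bottleneck
    cache$enc[[l]]$g_skip <- g_skip
    g <- upsample2_bwd(g_up)
  }
  # bottleneck
  bt <- cache$bot
  g2 <- g * (bt$a2 > 0)
  bw2 <- conv_bwd(bt$a1, w$bot_w2, g2, K)
  acc("bot_w2", "bot_b2", bw2)
  g1 <- bw2$gx * (bt$a1 > 0)
  bw1 <- conv_bwd(bt$input, w$bot_w1, g1, K)
  acc("bot_w1", "bot_b1", bw1)
  g <- bw1$gx
  # encoder, deepest level first
  for (l in rev(seq_len(cfg$depth))) {
    ec <- cache$enc[[l]]
    g_a2 <- nt_maxpool2_bwd(cache$pool[[l]], g, dim(ec$a2)[1], dim(ec$a2)[2])
    g_a2 <- g_a2 + ec$g_skip
    g2 <- g_a2 * (ec$a2 > 0)
    bw2 <- conv_bwd(ec$a1, w[[paste0("enc", l, "_w2")]], g2, K)
    acc(paste0("enc", l, "_w2"), paste0("enc", l, "_b2"), bw2)
    g1 <- bw2$gx * (ec$a1 > 0)
    bw1 <- conv_bwd(ec$input, w[[paste0("enc", l, "_w1")]], g1, K)
    acc(paste0("enc", l, "_w1"), paste0("enc", l, "_b1"), bw1)
    g <- bw1$gx
  }
  gr
}

# binary cross-entropy + soft Dice; returns loss, gradient w.r.t. logits,
# and the Dice score of the probability map
seg_loss_and_grad <- function(logits, mask) {
  m <- mask * 1
  p <- 1 / (1 + exp(-logits))
  n <- length(logits)
  bce <- mean(pmax(logits, 0) - logits * m + log1p(exp(-abs(logits))))
  s <- 1
  sp <- sum(p)
  sm <- sum(m)
  inter <- sum(p * m)
  dice <- (2 * inter + s) / (sp + sm + s)
  g_bce <- (p - m) / n
  d_dice_dp <- (2 * m * (sp + sm + s) - (2 * inter + s)) / (sp + sm + s)^2
  g_dice <- -d_dice_dp * p * (1 - p)
  list(loss = bce + (1 - dice), grad = g_bce + g_dice, dice = dice)
}

#' Train the needle-guide segmenter
#'
#' Trains the U-Net on paired images and binary masks with Adam, one step
#' per image per epoch in a seeded random order. Deterministic given
#' `cfg$rng_seed`.
#'
#' @param images List of real-valued `[0, 1]` image matrices.
#' @param masks List of logical mask matrices, paired with `images`.
#' @param cfg A [seg_config()].
#' @return An object of class `seg_model`: weights, config, and a
#'   `loss_trace` tibble (`epoch`, `loss`, `dice`).
#' @export
train_segmenter <- function(images, masks, cfg) {
  stopifnot(inherits(cfg, "seg_config"), length(images) == length(masks),
            length(images) >= 1)
  if (!any(vapply(masks, any, logical(1)))) {
    stop("all training masks are empty; nothing to segment")
  }
  n <- length(images)
  trace_loss <- numeric(cfg$epochs)
  trace_dice <- numeric(cfg$epochs)
  withr::with_seed(cfg$rng_seed, {
    w <- init_unet_weights(cfg)
    opt <- adam_init(w)
    for (ep in seq_len(cfg$epochs)) {
      tot <- 0
      totd <- 0
      for (s in sample(n)) {
        fw <- unet_forward(images[[s]], w, cfg, keep_cache = TRUE)
        lg <- seg_loss_and_grad(fw$logits, masks[[s]])
        if (!is.finite(lg$loss)) {
          stop("segmentation training diverged (non-finite loss) at epoch ",
               ep)
        }
        gr <- unet_backward(w, cfg, fw$cache, lg$grad)
        upd <- adam_step(w, gr, opt, cfg$learning_rate)
        w <- upd$params
        opt <- upd$state
        tot <- tot + lg$loss
        totd <- totd + lg$dice
      }
      trace_loss[ep] <- tot / n
      trace_dice[ep] <- totd / n
    }
  })
  structure(
    list(weights = w, cfg = cfg,
         loss_trace = tibble::tibble(epoch = seq_len(cfg$epochs),
                                     loss = trace_loss, dice = trace_dice)),
    class = "seg_model"
  )
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model> depth ", x$cfg$depth, ", ", x$cfg$base_filters,
      " base filters, trained ", nrow(x$loss_trace),
      " epochs (final Dice ",
      signif(utils::tail(x$loss_trace$dice, 1), 3), ")\n", sep = "")
  invisible(x)
}

#' Segment the needle guide in a reconstructed frame
#'
#' Deterministic inference: forward pass, sigmoid, threshold. Image
#' dimensions must be divisible by `2^depth`.
#'
#' @param image Real-valued `[0, 1]` matrix.
#' @param model A trained [train_segmenter()] result.
#' @return Logical mask matrix of the same shape.
#' @export
segment <- function(image, model) {
  stopifnot(inherits(model, "seg_model"), is.matrix(image))
  if (any(dim(image) %% 2^model$cfg$depth != 0)) {
    stop("image dimensions must be divisible by 2^depth = ",
         2^model$cfg$depth)
  }
  fw <- unet_forward(image, model$weights, model$cfg)
  mask <- 1 / (1 + exp(-fw$logits)) >= model$cfg$threshold
  if (model$cfg$keep_largest_component && any(mask)) {
    mask <- largest_component(mask)
  }
  mask
}

# largest 4-connected foreground component (simple two-pass queue fill)
largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  best <- NULL
  best_n <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    members <- start
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      i <- (p - 1) %% nrow(mask) + 1
      j <- (p - 1) %/% nrow(mask) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]
        jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask)) {
          q <- (jj - 1) * nrow(mask) + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
            members <- c(members, q)
          }
        }
      }
    }
    if (length(members) > best_n) {
      best_n <- length(members)
      best <- members
    }
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[best] <- TRUE
  out
}
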