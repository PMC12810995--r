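#' Configuration for a tracking experiment
#'
#' Defines the acceleration ladder and reconstruction methods swept by
#' [run_tracking_experiment()]. The ladder defaults to the eight factors of
#' the feasibility protocol (8x is the native acquisition, retaining the 32
#' central lines of a 256-line matrix; higher factors zero additional outer
#' lines); lower factors may be configured for synthetic studies.
#'
#' @param accelerations Strictly increasing acceleration factors.
#' @param methods Subset of `"zero_filled"`, `"crnn"`, `"oracle"` (the
#'   latter reconstructs fully sampled regardless of the ladder, isolating
#'   segmentation quality from reconstruction quality).
#' @param success_threshold_mm ITP success threshold. Default 5 mm.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(accelerations = c(8, 10, 12, 14, 16, 18, 20, 25),
                              methods = c("zero_filled", "crnn"),
                              success_threshold_mm = 5) {
  stopifnot(length(accelerations) >= 1, all(diff(accelerations) > 0),
            all(accelerations >= 1), success_threshold_mm > 0,
            all(methods %in% c("zero_filled", "crnn", "oracle")))
  structure(
    list(accelerations = accelerations, methods = methods,
         success_threshold_mm = success_threshold_mm),
    class = "experiment_config"
  )
}

# fully sampled RSS reconstruction of a single multi-coil k-space scan
full_rss_recon <- function(kspace) {
  if (length(dim(kspace)) == 2) dim(kspace) <- c(dim(kspace), 1L)
  imgs <- array(0 + 0i, dim = dim(kspace))
  for (c in seq_len(dim(kspace)[3])) {
    imgs[, , c] <- centered_ifft2(kspace[, , c])
  }
  rss_combine(imgs)
}

#' Run the tracking experiment on one dynamic sample
#'
#' The full per-sample pipeline: the fully sampled pre- and post-movement
#' scans are reconstructed by inverse Fourier transform and root sum of
#' squares and segmented; their tip estimates define the reference
#' trajectory by linear interpolation across the annotated motion window.
#' For every acceleration factor and method, the dynamic frames are masked
#' to the central lines, reconstructed (zero-filled, recurrent network, or
#' fully sampled oracle), intensity-scaled as a sequence, segmented, and the
#' guide tip is localized per frame by [pca_tip()]; the per-frame ITP error
#' against the reference is recorded. A failing stage marks the frame as an
#' invalid estimate (infinite error) rather than aborting the sample.
#'
#' @param sample A [generate_sample()] `dynamic_sample` (or a compatible
#'   list read back from disk).
#' @param cfg An [experiment_config()].
#' @param recon_model Trained [train_recon_model()] model (required when
#'   `"crnn"` is among the methods).
#' @param seg_model Trained [train_segmenter()] model (required unless
#'   `oracle_segmentation` is set).
#' @param oracle_segmentation Use the ground-truth masks instead of the
#'   segmenter (isolates reconstruction and tracking logic from
#'   segmentation quality).
#' @param sample_id Identifier recorded in the result rows.
#' @return A tibble of class `tracking_result` with one row per
#'   `(R, method, frame)`: predicted and reference tip positions (mm),
#'   `error_mm`, `success`, `excluded`, and the motion window.
#' @export
run_tracking_experiment <- function(sample, cfg = experiment_config(),
                                    recon_model = NULL, seg_model = NULL,
                                    oracle_segmentation = FALSE,
                                    sample_id = "sample-1") {
  stopifnot(inherits(cfg, "experiment_config"))
  if ("crnn" %in% cfg$methods && is.null(recon_model)) {
    stop("the 'crnn' method needs a trained reconstruction model")
  }
  if (!oracle_segmentation && is.null(seg_model)) {
    stop("need a trained segmentation model (or oracle_segmentation = TRUE)")
  }
  sp <- sample$spacing
  n_frames <- dim(sample$dyn_kspace)[4]
  g <- dim(sample$dyn_kspace)[1]
  seg_fun <- function(img, truth) {
    if (oracle_segmentation) truth else segment(img, seg_model)
  }
  pre_img <- scale_intensities(full_rss_recon(sample$pre_kspace))
  post_img <- scale_intensities(full_rss_recon(sample$post_kspace))
  pre_tip <- pca_tip(seg_fun(pre_img, sample$truth_pre_mask), sp)
  post_tip <- pca_tip(seg_fun(post_img, sample$truth_post_mask), sp)
  if (!pre_tip$valid || !post_tip$valid) {
    stop("pre/post-movement tip estimate is invalid; the sample has no ",
         "usable reference trajectory")
  }
  ref <- reference_trajectory(pre_tip$tip_mm, post_tip$tip_mm,
                              sample$move_window, n_frames)
  rows <- list()
  for (R in cfg$accelerations) {
    mask <- make_central_mask(g, R)
    for (method in cfg$methods) {
      mag <- switch(method,
        zero_filled = reconstruct_sequence(sample$dyn_kspace, mask),
        crnn = reconstruct_sequence(sample$dyn_kspace, mask, recon_model),
        oracle = reconstruct_sequence(sample$dyn_kspace,
                                      make_central_mask(g, 1))
      )
      mag <- scale_intensities(mag)
      pred <- matrix(NA_real_, n_frames, 2)
      err <- numeric(n_frames)
      for (f in seq_len(n_frames)) {
        tip <- tryCatch({
          m <- seg_fun(mag[, , f], sample$truth_masks[, , f])
          pca_tip(m, sp)
        }, error = function(e) NULL)
        if (is.null(tip) || !tip$valid) {
          err[f] <- Inf
        } else {
          pred[f, ] <- tip$tip_mm
          err[f] <- itp_error(tip, c(ref$row_mm[f], ref$col_mm[f]))
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sample_id, R = R, method = method,
        frame = seq_len(n_frames),
        pred_row_mm = pred[, 1], pred_col_mm = pred[, 2],
        ref_row_mm = ref$row_mm, ref_col_mm = ref$col_mm,
        error_mm = err,
        success = err < cfg$success_threshold_mm,
        excluded = seq_len(n_frames) %in% sample$excluded_frames,
        move_start = sample$move_window[1],
        move_end = sample$move_window[2]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tracking_result", class(out))
  out
}
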