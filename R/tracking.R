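#' Principal-axis tip localization from a segmentation mask
#'
#' Estimates the needle-guide tip from a binary mask: the centroid of the
#' foreground pixel coordinates is computed, the 2x2 coordinate covariance
#' is eigen-decomposed, and the principal eigenvector defines the guide's
#' main axis. The axis endpoints are the extreme scalar projections of the
#' foreground pixels onto that axis, and the tip is the endpoint nearer the
#' image centre (resolving the eigenvector sign ambiguity); an exact
#' centre-distance tie is broken toward the endpoint with the smaller row,
#' then column, coordinate. Pixel centres
#' sit at `(i + 0.5) * spacing` mm for 0-based index `i`; the image centre
#' is at `grid_size * spacing / 2`.
#'
#' The estimate is flagged invalid — never an error, so a dropout frame can
#' be scored as a tracking failure — when the mask is empty, has fewer than
#' two pixels, or is directionally degenerate (eigenvalues equal within
#' `1e-9`, e.g. an isotropic disc).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param spacing mm per pixel.
#' @param image_center Centre `c(row_mm, col_mm)`; defaults to the grid
#'   centre.
#' @return An object of class `tip_estimate`: list with `tip_mm`, `tip_px`
#'   (continuous 0-based pixel coordinates), `axis` (unit vector),
#'   `eigenvalue_ratio` and `valid`.
#' @export
pca_tip <- function(mask, spacing, image_center = NULL) {
  stopifnot(is.matrix(mask), spacing > 0)
  if (is.null(image_center)) {
    image_center <- c(nrow(mask), ncol(mask)) * spacing / 2
  }
  invalid <- structure(
    list(tip_mm = c(NA_real_, NA_real_), tip_px = c(NA_real_, NA_real_),
         axis = c(NA_real_, NA_real_), eigenvalue_ratio = NA_real_,
         valid = FALSE),
    class = "tip_estimate"
  )
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) return(invalid)
  pts <- unname((idx - 0.5) * spacing) # pixel-centre coordinates in mm
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1] - ev$values[2] <= 1e-9) return(invalid)
  v <- ev$vectors[, 1]
  t_all <- (pts[, 1] - ctr[1]) * v[1] + (pts[, 2] - ctr[2]) * v[2]
  ends <- rbind(ctr + min(t_all) * v, ctr + max(t_all) * v)
  d2 <- rowSums((ends - matrix(image_center, 2, 2, byrow = TRUE))^2)
  # exact centre-distance ties (symmetric masks) are broken toward the
  # endpoint with the smaller row, then column, coordinate; this keeps the
  # choice independent of the eigenvector's arbitrary sign
  tip <- if (abs(d2[1] - d2[2]) <= 1e-9 * max(1, d2[1])) {
    if (ends[1, 1] < ends[2, 1] ||
          (ends[1, 1] == ends[2, 1] && ends[1, 2] <= ends[2, 2])) {
      ends[1, ]
    } else {
      ends[2, ]
    }
  } else {
    ends[which.min(d2), ]
  }
  structure(
    list(tip_mm = tip, tip_px = tip / spacing - 0.5, axis = v,
         eigenvalue_ratio = ev$values[1] / max(ev$values[2], .Machine$double.eps),
         valid = TRUE),
    class = "tip_estimate"
  )
}

#' @export
print.tip_estimate <- function(x, ...) {
  if (x$valid) {
    cat("<tip_estimate> tip (", signif(x$tip_mm[1], 5), ", ",
        signif(x$tip_mm[2], 5), ") mm, eigenvalue ratio ",
        signif(x$eigenvalue_ratio, 4), "\n", sep = "")
  } else {
    cat("<tip_estimate> invalid (empty or degenerate mask)\n")
  }
  invisible(x)
}

#' Reference tip trajectory by linear interpolation
#'
#' Builds the per-frame reference tip positions: constant at `pre_tip`
#' before the annotated motion window, constant at `post_tip` after it, and
#' linear in the frame index inside it, with `pre_tip` at the window start
#' and `post_tip` at the window end.
#'
#' @param pre_tip,post_tip Tip positions `c(row_mm, col_mm)` from the pre-
#'   and post-movement segmentations.
#' @param move_window Inclusive 1-based frame interval `c(start, end)`.
#' @param n_frames Number of dynamic frames.
#' @return Tibble with columns `frame`, `row_mm`, `col_mm`.
#' @export
reference_trajectory <- function(pre_tip, post_tip, move_window, n_frames) {
  stopifnot(length(pre_tip) == 2, length(post_tip) == 2,
            length(move_window) == 2, n_frames >= 1)
  s <- move_window[1]
  e <- move_window[2]
  if (s < 1 || e > n_frames || s > e) {
    stop("invalid motion window [", s, ", ", e, "] for ", n_frames,
         " frames")
  }
  frac <- vapply(seq_len(n_frames), function(f) {
    if (f <= s) 0 else if (f >= e) 1 else (f - s) / (e - s)
  }, numeric(1))
  tibble::tibble(
    frame = seq_len(n_frames),
    row_mm = pre_tip[1] + frac * (post_tip[1] - pre_tip[1]),
    col_mm = pre_tip[2] + frac * (post_tip[2] - pre_tip[2])
  )
}

#' Instrument tip prediction (ITP) error
#'
#' Euclidean distance in millimetres between a predicted tip and the
#' reference position for that frame. An invalid tip estimate yields `Inf`,
#' so the frame scores as a guaranteed tracking failure.
#'
#' @param pred A [pca_tip()] `tip_estimate`, or a numeric `c(row_mm,
#'   col_mm)` position.
#' @param ref Reference position `c(row_mm, col_mm)`.
#' @return Distance in mm.
#' @export
itp_error <- function(pred, ref) {
  p <- if (inherits(pred, "tip_estimate")) {
    if (!pred$valid) return(Inf)
    pred$tip_mm
  } else {
    pred
  }
  stopifnot(length(p) == 2, length(ref) == 2)
  sqrt(sum((p - ref)^2))
}
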