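#' Centered orthonormal 2D Fourier transforms
#'
#' Forward and inverse two-dimensional discrete Fourier transforms with
#' orthonormal scaling (`1/sqrt(N)` in each direction) and the zero-frequency
#' (DC) component at matrix index `grid_size/2` in 0-based terms, i.e. row and
#' column `grid_size/2 + 1` in R's 1-based indexing. Orthonormal scaling makes
#' the pair unitary, so Parseval's identity holds exactly:
#' `sum(Mod(x)^2) == sum(Mod(centered_fft2(x))^2)`.
#'
#' @param image Square complex (or numeric) matrix in image space.
#' @param kspace Square complex matrix in k-space.
#' @return A complex matrix of the same dimension.
#' @examples
#' x <- matrix(rnorm(16), 4, 4)
#' k <- centered_fft2(x)
#' max(Mod(centered_ifft2(k) - x)) < 1e-12
#' @export
centered_fft2 <- function(image) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  fftshift2(stats::fft(ifftshift2(image))) / sqrt(length(image))
}

#' @rdname centered_fft2
#' @export
centered_ifft2 <- function(kspace) {
  stopifnot(is.matrix(kspace), nrow(kspace) == ncol(kspace))
  fftshift2(stats::fft(ifftshift2(kspace), inverse = TRUE)) / sqrt(length(kspace))
}

# circular shifts taking the DC bin between corner (FFT-native) and center
fftshift2 <- function(x) {
  n <- dim(x)
  x[c((n[1] / 2 + 1):n[1], 1:(n[1] / 2)), c((n[2] / 2 + 1):n[2], 1:(n[2] / 2))]
}
ifftshift2 <- fftshift2 # even dimensions: shift is its own inverse

#' Central (ACS-style) phase-encoding sampling mask
#'
#' Builds the retention pattern for Cartesian centre-line undersampling: of
#' `n_phase` phase-encoding lines, only a contiguous central block of
#' `floor(n_phase / R)` lines around the zero-frequency line is retained, the
#' rest are zeroed. This mirrors an acquisition that keeps only the
#' autocalibration (ACS) lines of a parallel-imaging scan: at a 256-line
#' matrix, `R = 8` retains the 32 central lines. When the retained count is
#' odd the extra line sits on the lower-index side of the centre.
#'
#' @param n_phase Total number of phase-encoding lines (even).
#' @param R Nominal acceleration factor, `>= 1`.
#' @return An object of class `sampling_mask`: a list with `n_phase`,
#'   `retained` (logical per line), `nominal_R` and `n_retained`.
#' @seealso [escalate_mask()], [apply_mask()]
#' @examples
#' make_central_mask(256, 8)$n_retained # 32
#' make_central_mask(256, 12)$n_retained # 21
#' @export
make_central_mask <- function(n_phase, R) {
  stopifnot(length(n_phase) == 1, n_phase > 0, n_phase %% 2 == 0,
            length(R) == 1, R >= 1)
  n_ret <- floor(n_phase / R)
  if (n_ret < 1) {
    stop("acceleration R = ", R, " leaves no retained line out of ", n_phase)
  }
  dc <- n_phase / 2 # 0-based index of the zero-frequency line
  start <- dc - ceiling(n_ret / 2) # 0-based first retained line
  retained <- rep(FALSE, n_phase)
  retained[(start + 1):(start + n_ret)] <- TRUE
  structure(
    list(n_phase = n_phase, retained = retained,
         nominal_R = R, n_retained = n_ret),
    class = "sampling_mask"
  )
}

#' @export
print.sampling_mask <- function(x, ...) {
  idx <- which(x$retained) - 1L
  cat("<sampling_mask> ", x$n_retained, "/", x$n_phase,
      " lines retained (nominal R = ", x$nominal_R, "), 0-based block [",
      min(idx), ", ", max(idx), "]\n", sep = "")
  invisible(x)
}

#' Escalate a central mask to a higher acceleration
#'
#' Removes outer lines symmetrically from both edges of the retained central
#' block until the pattern equals `make_central_mask(n_phase, target_R)`; e.g.
#' escalating a 32-line block from 8x to 16x zeroes the 8 outermost lines on
#' each side, leaving 16.
#'
#' @param mask A [make_central_mask()] result.
#' @param target_R Target acceleration, `>= mask$nominal_R`.
#' @return A `sampling_mask` at the higher acceleration.
#' @export
escalate_mask <- function(mask, target_R) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (target_R < mask$nominal_R) {
    stop("target_R (", target_R, ") is below the current acceleration (",
         mask$nominal_R, "); escalation only removes lines")
  }
  out <- make_central_mask(mask$n_phase, target_R)
  stopifnot(all(mask$retained[out$retained])) # escalation only zeroes lines
  out
}

#' Zero the unsampled phase-encoding lines of a k-space grid
#'
#' Phase encoding runs along the row axis of the stored grid (the frequency
#' axis is always fully sampled, as in a Cartesian acquisition); rows whose
#' lines are retained are copied verbatim, all others are set to exactly zero.
#'
#' @param kspace Complex matrix (one coil) or 3D array (row, col, coil).
#' @param mask A `sampling_mask` with `n_phase == nrow(kspace)`.
#' @return Masked k-space of the same shape.
#' @export
apply_mask <- function(kspace, mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  d <- dim(kspace)
  if (d[1] != mask$n_phase) {
    stop("k-space has ", d[1], " phase lines but the mask expects ",
         mask$n_phase)
  }
  out <- kspace
  if (length(d) == 2) {
    out[!mask$retained, ] <- 0
  } else {
    out[!mask$retained, , ] <- 0
  }
  out
}

#' Root-sum-of-squares coil combination
#'
#' @param coil_images Complex/numeric 3D array (row, col, coil) or a list of
#'   matrices, one per coil.
#' @return Non-negative magnitude matrix: per pixel,
#'   `sqrt(sum_c |image_c|^2)`.
#' @export
rss_combine <- function(coil_images) {
  if (is.list(coil_images)) {
    coil_images <- simplify2array(coil_images)
  }
  if (length(dim(coil_images)) == 2) {
    dim(coil_images) <- c(dim(coil_images), 1L)
  }
  sqrt(apply(Mod(coil_images)^2, c(1, 2), sum))
}

#' Zero-filled reconstruction of undersampled multi-coil k-space
#'
#' The baseline reconstruction used throughout: unsampled lines are left at
#' zero, each coil is inverse-Fourier-transformed, and coils are combined by
#' root sum of squares. With a full mask and one coil this reproduces the
#' magnitude image exactly; with few central lines it yields the familiar
#' phase-direction blur.
#'
#' @param kspace Complex matrix (single coil) or 3D array (row, col, coil).
#' @param mask A `sampling_mask`.
#' @return Magnitude image matrix.
#' @export
zero_fill_reconstruct <- function(kspace, mask) {
  ks <- apply_mask(kspace, mask)
  if (length(dim(ks)) == 2) {
    dim(ks) <- c(dim(ks), 1L)
  }
  imgs <- array(0 + 0i, dim = dim(ks))
  for (c in seq_len(dim(ks)[3])) {
    imgs[, , c] <- centered_ifft2(ks[, , c])
  }
  rss_combine(imgs)
}

#' Scale an image sequence to the unit intensity range
#'
#' Affine rescale using the global minimum and maximum over the whole
#' sequence (not per frame), so relative intensity dynamics across time are
#' preserved. A constant sequence maps to all zeros.
#'
#' @param images List of numeric matrices, a single matrix, or a 3D array
#'   with frames along the third dimension.
#' @return Same structure with values in `[0, 1]`.
#' @export
scale_intensities <- function(images) {
  single <- is.matrix(images)
  as_list <- if (single) list(images) else if (is.array(images) && length(dim(images)) == 3) {
    lapply(seq_len(dim(images)[3]), function(f) images[, , f])
  } else {
    images
  }
  lo <- min(vapply(as_list, min, numeric(1)))
  hi <- max(vapply(as_list, max, numeric(1)))
  out <- if (hi > lo) {
    lapply(as_list, function(m) (m - lo) / (hi - lo))
  } else {
    lapply(as_list, function(m) m * 0)
  }
  if (single) return(out[[1]])
  if (is.array(images) && length(dim(images)) == 3) {
    return(simplify2array(out))
  }
  out
}

#' Protocol arithmetic: effective undersampling and scan time
#'
#' `effective_undersampling()` is the ratio of encoded to acquired
#' phase-encoding lines, reported to one decimal (a 320-line encode acquired
#' with 68 lines is 4.7x). `scan_time()` is `TR x lines x units` in seconds to
#' two decimals, where `n_units` counts slices or dynamic frames (a 4.56 ms TR
#' over 320 lines and 5 slices gives 7.30 s).
#'
#' @param encoded_lines,acquired_lines Positive line counts.
#' @param tr_ms Repetition time in milliseconds.
#' @param n_lines Acquired phase-encoding lines per unit.
#' @param n_units Number of slices or frames (0 allowed, giving 0 s).
#' @return A single number (ratio, or seconds).
#' @export
effective_undersampling <- function(encoded_lines, acquired_lines) {
  stopifnot(encoded_lines > 0, acquired_lines > 0)
  round(encoded_lines / acquired_lines, 1)
}

#' @rdname effective_undersampling
#' @export
scan_time <- function(tr_ms, n_lines, n_units) {
  stopifnot(tr_ms > 0, n_lines > 0, n_units >= 0)
  round(tr_ms * n_lines * n_units / 1000, 2)
}

#' Serialize a sampling mask to/from JSON
#'
#' Stores the 0-based retained line indices together with the line count and
#' nominal acceleration, for bit-exact exchange with other tools.
#'
#' @param mask A `sampling_mask`.
#' @param path File path.
#' @return `mask_from_json()` returns the reconstructed `sampling_mask`.
#' @export
mask_to_json <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  jsonlite::write_json(
    list(n_phase = mask$n_phase, nominal_R = mask$nominal_R,
         retained_lines_0based = which(mask$retained) - 1L),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname mask_to_json
#' @export
mask_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  retained <- rep(FALSE, x$n_phase)
  retained[x$retained_lines_0based + 1L] <- TRUE
  structure(
    list(n_phase = as.integer(x$n_phase), retained = retained,
         nominal_R = x$nominal_R, n_retained = sum(retained)),
    class = "sampling_mask"
  )
}
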