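# success/failure colour ramps for the per-frame error heatmap: successes
# (error below threshold) in blues, failures in reds, excluded frames blank
heatmap_colors <- function(error_mm, excluded, threshold = 5) {
  blue <- grDevices::colorRamp(c("#deebf7", "#08519c"))
  red <- grDevices::colorRamp(c("#fcbba1", "#67000d"))
  vapply(seq_along(error_mm), function(i) {
    if (excluded[i]) return(NA_character_)
    e <- error_mm[i]
    if (e < threshold) {
      v <- blue(min(e / threshold, 1))
    } else {
      v <- red(min((min(e, 4 * threshold) - threshold) / (3 * threshold), 1))
    }
    grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)
  }, character(1))
}

#' Per-frame ITP error heatmap
#'
#' Samples-by-frames tile plot of the tracking errors for one acceleration
#' factor and method: successes (error below the threshold) in a blue ramp,
#' failures in a red ramp, excluded frames blanked, and the annotated
#' motion window outlined per sample.
#'
#' @param results A [run_tracking_experiment()] tibble (rows for several
#'   samples may be bound together).
#' @param R,method Acceleration factor and method to display; default the
#'   first present.
#' @param threshold Success threshold in mm. Default 5.
#' @return A ggplot object.
#' @export
plot_error_heatmap <- function(results, R = NULL, method = NULL,
                               threshold = 5) {
  if (is.null(R)) R <- results$R[1]
  if (is.null(method)) method <- results$method[1]
  df <- dplyr::filter(results, .data$R == !!R, .data$method == !!method)
  stopifnot(nrow(df) > 0)
  df$fill <- heatmap_colors(df$error_mm, df$excluded, threshold)
  win <- dplyr::distinct(df, .data$sample_id, .data$move_start,
                         .data$move_end)
  win$y <- match(win$sample_id, unique(df$sample_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$sample_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), color = "grey85") +
    ggplot2::scale_fill_identity(na.value = "white") +
    ggplot2::geom_rect(
      data = win, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$move_start - 0.5,
                   xmax = .data$move_end + 0.5,
                   ymin = .data$y - 0.5, ymax = .data$y + 0.5),
      fill = NA, color = "white", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "frame", y = "sample",
      title = sprintf("ITP error heatmap, %gx (%s)", R, method),
      subtitle = sprintf(
        "blue: success (< %g mm), red: failure, blank: excluded", threshold)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_error_heatmap
#' @param object A `tracking_result` tibble.
#' @param ... Passed to `plot_error_heatmap()`.
#' @exportS3Method ggplot2::autoplot
autoplot.tracking_result <- function(object, ...) {
  plot_error_heatmap(object, ...)
}

#' Write a deterministic PNG error heatmap
#'
#' Renders the samples-by-frames error grid directly to PNG (no graphics
#' device), so identical inputs give byte-identical files. Each cell is a
#' `cell_px` square; excluded frames are white and the motion window is
#' outlined in white.
#'
#' @inheritParams plot_error_heatmap
#' @param path Output file path (`.png`).
#' @param cell_px Pixels per cell. Default 8.
#' @return The path, invisibly.
#' @export
write_error_heatmap <- function(results, path, R = NULL, method = NULL,
                                threshold = 5, cell_px = 8) {
  if (is.null(R)) R <- results$R[1]
  if (is.null(method)) method <- results$method[1]
  df <- dplyr::filter(results, .data$R == !!R, .data$method == !!method)
  stopifnot(nrow(df) > 0)
  samples <- unique(df$sample_id)
  frames <- sort(unique(df$frame))
  img <- array(1, dim = c(length(samples), length(frames), 3))
  for (r in seq_along(samples)) {
    rows <- df[df$sample_id == samples[r], ]
    cols <- heatmap_colors(rows$error_mm, rows$excluded, threshold)
    for (fidx in seq_along(frames)) {
      cl <- cols[rows$frame == frames[fidx]]
      if (length(cl) == 1 && !is.na(cl)) {
        img[r, fidx, ] <- grDevices::col2rgb(cl)[, 1] / 255
      }
    }
  }
  up <- function(m, k) m[rep(seq_len(nrow(m)), each = k),
                         rep(seq_len(ncol(m)), each = k)]
  big <- array(0, dim = c(nrow(img) * cell_px, ncol(img) * cell_px, 3))
  for (ch in 1:3) big[, , ch] <- up(img[, , ch], cell_px)
  # outline the motion window in white
  win <- dplyr::distinct(df, .data$sample_id, .data$move_start, .data$move_end)
  for (r in seq_len(nrow(win))) {
    y <- match(win$sample_id[r], samples)
    x0 <- (win$move_start[r] - 1) * cell_px + 1
    x1 <- win$move_end[r] * cell_px
    y0 <- (y - 1) * cell_px + 1
    y1 <- y * cell_px
    big[c(y0, y1), x0:x1, ] <- 1
    big[y0:y1, c(x0, x1), ] <- 1
  }
  png::writePNG(big, path)
  invisible(path)
}
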