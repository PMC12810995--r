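# On-disk interchange for samples and results: NIfTI volumes for images,
# masks and (real/imaginary) k-space, CSV for tip tables, YAML for configs,
# JSON for sampling masks. Model checkpoints are R serializations.

write_nifti_array <- function(x, path, spacing) {
  img <- RNifti::asNifti(x, pixdim = rep(spacing, min(3, length(dim(x)))))
  RNifti::writeNifti(img, path)
}

#' Write/read a dynamic sample as a directory of standard files
#'
#' Serializes a [generate_sample()] result to `dir`: complex k-space as
#' paired real/imaginary NIfTI volumes (`dyn_*`, `pre_*`, `post_*`), the
#' ground-truth masks as NIfTI, the tip table as CSV, and the geometry plus
#' generator configuration as YAML. `read_sample()` restores the
#' `dynamic_sample` object bit-exactly up to floating-point serialization.
#'
#' @param sample A `dynamic_sample`.
#' @param dir Output directory (created if needed).
#' @return `write_sample()` the directory path invisibly; `read_sample()` a
#'   `dynamic_sample`.
#' @export
write_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "dynamic_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- sample$spacing
  write_nifti_array(Re(sample$dyn_kspace), file.path(dir, "dyn_real.nii.gz"), sp)
  write_nifti_array(Im(sample$dyn_kspace), file.path(dir, "dyn_imag.nii.gz"), sp)
  write_nifti_array(Re(sample$pre_kspace), file.path(dir, "pre_real.nii.gz"), sp)
  write_nifti_array(Im(sample$pre_kspace), file.path(dir, "pre_imag.nii.gz"), sp)
  write_nifti_array(Re(sample$post_kspace), file.path(dir, "post_real.nii.gz"), sp)
  write_nifti_array(Im(sample$post_kspace), file.path(dir, "post_imag.nii.gz"), sp)
  write_nifti_array(sample$truth_masks * 1, file.path(dir, "truth_masks.nii.gz"), sp)
  write_nifti_array(sample$truth_pre_mask * 1, file.path(dir, "pre_mask.nii.gz"), sp)
  write_nifti_array(sample$truth_post_mask * 1, file.path(dir, "post_mask.nii.gz"), sp)
  utils::write.csv(sample$truth_tips, file.path(dir, "truth_tips.csv"),
                   row.names = FALSE)
  yaml::write_yaml(
    c(list(move_window = sample$move_window,
           excluded_frames = sample$excluded_frames,
           spacing = sample$spacing),
      list(config = unclass(sample$config))),
    file.path(dir, "sample.yaml")
  )
  invisible(dir)
}

#' @rdname write_sample
#' @export
read_sample <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "sample.yaml"))
  rd <- function(name) {
    as.array(RNifti::readNifti(file.path(dir, name)))
  }
  cplx <- function(stem) {
    re <- rd(paste0(stem, "_real.nii.gz"))
    im <- rd(paste0(stem, "_imag.nii.gz"))
    array(complex(real = re, imaginary = im), dim = dim(re))
  }
  cfg <- meta$config
  cfg$move_window <- as.integer(cfg$move_window)
  cfg$excluded_frames <- as.integer(cfg$excluded_frames)
  class(cfg) <- "phantom_config"
  dyn <- cplx("dyn")
  if (length(dim(dyn)) == 3) { # single-coil samples round-trip as 3D
    dim(dyn) <- c(dim(dyn)[1:2], 1L, dim(dyn)[3])
  }
  structure(
    list(pre_kspace = ensure_coil_dim(cplx("pre")),
         dyn_kspace = dyn,
         post_kspace = ensure_coil_dim(cplx("post")),
         truth_tips = tibble::as_tibble(
           utils::read.csv(file.path(dir, "truth_tips.csv"))),
         truth_masks = rd("truth_masks.nii.gz") != 0,
         truth_pre_mask = as.matrix(rd("pre_mask.nii.gz"))[, ] != 0,
         truth_post_mask = as.matrix(rd("post_mask.nii.gz"))[, ] != 0,
         move_window = as.integer(meta$move_window),
         excluded_frames = as.integer(meta$excluded_frames),
         spacing = meta$spacing, config = cfg),
    class = "dynamic_sample"
  )
}

ensure_coil_dim <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x
}

#' Write a per-frame tip table to CSV
#'
#' Emits the standard tracking table (frame, predicted and reference tip
#' positions in mm, error and success flag) for one or more experiment
#' rows.
#'
#' @param results A [run_tracking_experiment()] tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tracking_csv <- function(results, path) {
  cols <- c("sample_id", "R", "method", "frame", "pred_row_mm",
            "pred_col_mm", "ref_row_mm", "ref_col_mm", "error_mm",
            "success", "excluded")
  utils::write.csv(results[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Save/load a trained model checkpoint
#'
#' Stores the weights together with the embedded configuration (including
#' the seed) in a single file.
#'
#' @param model A `crnn_model` or `seg_model`.
#' @param path Checkpoint path.
#' @return `load_model()` returns the model object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "crnn_model") || inherits(model, "seg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "crnn_model") || inherits(model, "seg_model"))
  model
}
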