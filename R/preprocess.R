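#' CT slice preparation chain
#'
#' The image-preparation steps applied to every CT slice before training or
#' inference: conversion of stored pixel values to Hounsfield units (HU),
#' window/level contrast adjustment, contrast-limited adaptive histogram
#' equalization (CLAHE) of the windowed slice, and a final min-max
#' normalization to \code{[0,1]}.
#'
#' @name preprocess
NULL

check_finite_grid <- function(x, what = "image") {
  if (!is.matrix(x) || length(x) == 0)
    stop(what, " must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Convert stored pixel values to Hounsfield units
#'
#' Applies the affine rescale \code{HU = pixel * slope + intercept}. For PNG
#' input without calibration metadata use \code{slope = 1, intercept = 0}
#' (the step is then the identity).
#'
#' @param pixels Matrix of stored pixel values.
#' @param slope,intercept Rescale slope (> 0) and intercept from the
#'   acquisition metadata.
#' @return Matrix of HU values, same shape as the input.
#' @export
#' @examples
#' to_hounsfield(matrix(c(0, 1000), 1), slope = 1, intercept = -1024)
to_hounsfield <- function(pixels, slope = 1, intercept = 0) {
  check_finite_grid(pixels, "pixels")
  if (!is.finite(slope) || !is.finite(intercept))
    stop("slope and intercept must be finite", call. = FALSE)
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  pixels * slope + intercept
}

#' Window/level contrast adjustment
#'
#' Clips HU values to the band \code{[level - width/2, level + width/2]} and
#' maps the band linearly to \code{[0,1]}. The default 60/400 window is a
#' standard abdominal soft-tissue window in which liver parenchyma and bile
#' are both visible.
#'
#' @param hu Matrix of HU values.
#' @param level Window centre in HU.
#' @param width Window width in HU (> 0).
#' @return Matrix in \code{[0,1]}, same shape.
#' @export
#' @examples
#' apply_window(matrix(c(-500, 60, 160), 1), level = 60, width = 400)
apply_window <- function(hu, level = 60, width = 400) {
  check_finite_grid(hu, "hu")
  if (!is.finite(width) || width <= 0)
    stop("window width must be positive", call. = FALSE)
  lo <- level - width / 2
  pmin(pmax((hu - lo) / width, 0), 1)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit, applied to a
#' normalized slice to sharpen the local contrast around the organ
#' boundaries. The computation is delegated to \code{EBImage::clahe};
#' \code{clip_limit} is expressed as the maximum fraction of a tile's pixels
#' allowed in a single histogram bin before redistribution (the scale used
#' by most image-processing toolkits) and converted to EBImage's multiplier
#' of the mean bin count internally.
#'
#' @param img Matrix in \code{[0,1]}.
#' @param clip_limit Positive clip limit on the normalized scale
#'   (default 0.01).
#' @param tile_grid Integer pair: number of tiles along each axis
#'   (default 8x8).
#' @param bins Histogram bins per tile.
#' @return Matrix in \code{[0,1]}, same shape. A constant input is returned
#'   unchanged (there is no contrast to equalize).
#' @export
equalize_adaptive <- function(img, clip_limit = 0.01, tile_grid = c(8L, 8L),
                              bins = 256L) {
  check_finite_grid(img)
  if (!is.finite(clip_limit) || clip_limit <= 0)
    stop("clip_limit must be positive", call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop("img must lie in [0,1]; window or normalize it first", call. = FALSE)
  rng <- range(img)
  if (diff(rng) < 1e-12) return(img)
  out <- EBImage::clahe(EBImage::Image(img), nx = tile_grid[1], ny = tile_grid[2],
                        bins = bins, limit = clip_limit * bins,
                        keep.range = FALSE)
  out <- EBImage::imageData(out)
  pmin(pmax(out, 0), 1)
}

#' Min-max normalization to [0,1]
#'
#' \code{(x - min)/(max - min)}; a constant grid maps to all zeros so that
#' padding-only slices do not abort a batch.
#'
#' @param img Non-empty finite matrix.
#' @return Matrix in \code{[0,1]}, same shape.
#' @export
#' @examples
#' normalize01(matrix(c(2, 4, 6), 1))
normalize01 <- function(img) {
  check_finite_grid(img)
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Run the full preparation chain on one slice
#'
#' \code{to_hounsfield} then \code{apply_window} then
#' \code{equalize_adaptive} then \code{normalize01}.
#'
#' @inheritParams to_hounsfield
#' @inheritParams apply_window
#' @inheritParams equalize_adaptive
#' @return Matrix in \code{[0,1]} with the input's shape.
#' @export
preprocess_slice <- function(pixels, slope = 1, intercept = 0,
                             level = 60, width = 400,
                             clip_limit = 0.01, tile_grid = c(8L, 8L)) {
  hu <- to_hounsfield(pixels, slope, intercept)
  win <- apply_window(hu, level, width)
  eq <- equalize_adaptive(win, clip_limit, tile_grid)
  normalize01(eq)
}

## ---- slice I/O -----------------------------------------------------------

#' Read and write grayscale slices
#'
#' Thin wrappers over the \pkg{png} and \pkg{RNifti} readers. PNG slices are
#' returned on their stored \code{[0,1]} scale (so the HU step is the
#' identity with \code{slope = 1, intercept = 0}); NIfTI volumes are read as
#' stored values with one matrix per axial slice.
#'
#' @param path File path.
#' @return \code{read_slice_png}: a matrix. \code{read_slices_nifti}: a list
#'   of matrices, one per axial slice.
#' @export
read_slice_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' @rdname read_slice_png
#' @export
read_slices_nifti <- function(path) {
  v <- RNifti::readNifti(path)
  v <- as.array(v)
  if (length(dim(v)) == 2) return(list(v))
  lapply(seq_len(dim(v)[3]), function(k) v[, , k])
}

#' @rdname read_slice_png
#' @param img Matrix in \code{[0,1]} to write.
#' @export
write_slice_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname read_slice_png
#' @param slices A matrix or list of equally sized matrices (stacked along
#'   the third axis).
#' @export
write_slices_nifti <- function(slices, path) {
  if (is.matrix(slices)) slices <- list(slices)
  vol <- array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Preprocess a directory of slices
#'
#' Applies \code{\link{preprocess_slice}} to every PNG (or every axial slice
#' of every NIfTI volume) in a directory, writes the prepared slices as PNG,
#' and echoes the preprocessing parameters to a JSON sidecar.
#'
#' @param input_dir,out_dir Input and output directories.
#' @param format \code{"png"} or \code{"nifti"}.
#' @inheritParams preprocess_slice
#' @return Invisibly, a tibble listing the written files.
#' @export
preprocess_dir <- function(input_dir, out_dir, format = c("png", "nifti"),
                           slope = 1, intercept = 0, level = 60, width = 400,
                           clip_limit = 0.01, tile_grid = c(8L, 8L)) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(input_dir, full.names = TRUE,
                      pattern = if (format == "png") "\\.png$" else "\\.nii(\\.gz)?$")
  written <- character(0)
  for (f in files) {
    slices <- if (format == "png") list(read_slice_png(f)) else read_slices_nifti(f)
    for (k in seq_along(slices)) {
      out <- preprocess_slice(slices[[k]], slope, intercept, level, width,
                              clip_limit, tile_grid)
      nm <- sprintf("%s%s.png", sub("\\.(png|nii|nii\\.gz)$", "", basename(f)),
                    if (length(slices) > 1) sprintf("_s%03d", k) else "")
      write_slice_png(out, file.path(out_dir, nm))
      written <- c(written, nm)
    }
  }
  jsonlite::write_json(
    list(format = format, slope = slope, intercept = intercept, level = level,
         width = width, clip_limit = clip_limit, tile_grid = tile_grid),
    file.path(out_dir, "preprocess_params.json"), auto_unbox = TRUE)
  invisible(tibble::tibble(file = written))
}
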