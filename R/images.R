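#' Crop a square patch with mean padding and bilinear resampling
#'
#' Extracts the square window of side `crop_side` (image pixels, sub-pixel
#' allowed) centred at `center` and resamples it bilinearly to
#' `out_size` x `out_size`. Samples falling outside the image are filled
#' with the image mean intensity (or `fill` if given), the standard
#' border handling for exemplar/search crops near frame edges.
#'
#' @param image numeric or integer matrix (rows = y, cols = x).
#' @param center `c(x, y)` in 0-based pixel-centre coordinates.
#' @param crop_side side of the source window in pixels (> 0).
#' @param out_size output side in pixels.
#' @param fill padding value; defaults to `mean(image)`.
#' @return `out_size` x `out_size` numeric matrix.
#' @export
crop_patch <- function(image, center, crop_side, out_size,
                       fill = mean(image)) {
  if (any(!is.finite(center))) stop("crop center must be finite")
  if (!is.finite(crop_side) || crop_side <= 0)
    stop("crop_side must be positive")
  cpp_crop_resize(matrix(as.numeric(image), nrow(image), ncol(image)),
                  center[1], center[2], crop_side, as.integer(out_size),
                  fill)
}

#' Bicubic score-map upsampling
#'
#' Upsamples a raw score map by an integer factor with corner-aligned
#' Catmull-Rom bicubic interpolation: an `n` x `n` grid becomes
#' `((n-1)*factor + 1)` squared, every raw cell is reproduced exactly, and
#' the grid centre of an odd-sized map stays an exact output cell. Constant
#' grids are preserved exactly.
#'
#' @param grid numeric matrix.
#' @param factor integer upsampling factor (>= 1; 1 returns the input).
#' @return upsampled numeric matrix.
#' @export
upsample_score <- function(grid, factor) {
  if (!is.finite(factor) || factor < 1 || factor != round(factor))
    stop("upsample factor must be an integer >= 1")
  cpp_upsample_bicubic(grid, as.integer(factor))
}
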