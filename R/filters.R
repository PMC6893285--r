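#' Rank and linear filters with reflect boundary handling
#'
#' Thin wrappers around the compiled filter kernels shared by the spot caller
#' and the segmentation routines. All filters use symmetric (reflect) padding
#' in which the edge pixel is repeated, and even-sized windows are anchored
#' with the extra row/column toward larger indices (a `w x w` window covers
#' offsets `-(w-1)%/%2 .. w%/%2`).
#'
#' @param img Numeric `Y x X` matrix.
#' @param size Window size in pixels; either a single size for a square
#'   window or `c(wy, wx)`.
#' @return A matrix of the same shape as `img`.
#' @name image-filters
NULL

check_window <- function(img, size, stage) {
  size <- as.integer(rep(size, length.out = 2L))
  if (any(size < 1L)) abort(paste0(stage, ": window size must be >= 1 px."))
  if (size[1L] > nrow(img) || size[2L] > ncol(img)) {
    abort(sprintf(
      "%s: image (%d x %d px) is smaller than the %d x %d filter window.",
      stage, nrow(img), ncol(img), size[1L], size[2L]
    ))
  }
  size
}

#' @rdname image-filters
#' @param stage Label used in error messages when the window does not fit.
#' @export
median_filter <- function(img, size, stage = "median filter") {
  size <- check_window(img, size, stage)
  median_filter_cpp(img, size[1L], size[2L])
}

#' @rdname image-filters
#' @export
mean_filter <- function(img, size, stage = "mean filter") {
  size <- check_window(img, size, stage)
  mean_filter_cpp(img, size[1L], size[2L])
}

#' @rdname image-filters
#' @param sigma Gaussian standard deviation in pixels.
#' @export
gaussian_filter <- function(img, sigma) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  gaussian_filter_cpp(img, sigma)
}

#' @rdname image-filters
#' @export
laplacian <- function(img) {
  laplacian_cpp(img)
}

#' Connected-component labelling
#'
#' @param mask Logical matrix of foreground pixels.
#' @param connectivity Neighbour rule, 4 or 8 (default 8).
#' @return Integer matrix of labels; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8.")
  label_components_cpp(mask, as.integer(connectivity))
}

#' Robust noise scale of an image
#'
#' Median absolute deviation from the median, scaled to be consistent with
#' the standard deviation under a Gaussian model. Used for automatic
#' intensity-rejection thresholds.
#'
#' @param img Numeric matrix or vector.
#' @return A single nonnegative number.
#' @export
mad_sd <- function(img) {
  stats::mad(as.numeric(img), constant = 1.4826)
}
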