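#' Calibrated image hyper-stack
#'
#' The carrier of all raw imagery in the package: a 4-D nonnegative intensity
#' array in fixed `T x Z x Y x X` order together with its physical
#' calibration. `Y` is the row (vertical) axis and `X` the column axis of each
#' frame; pixel coordinates reported elsewhere are 0-based pixel centres.
#'
#' @param data Numeric array. A `T x Z x Y x X` array, or a `Y x X` matrix /
#'   `T x Y x X` array which are promoted by inserting singleton dimensions
#'   (a matrix becomes one frame, one slice; a 3-D array is read as
#'   `T x Y x X` with a single z-slice).
#' @param pixel_size_um Lateral pixel size in micrometres (> 0).
#' @param z_step_um Axial slice spacing in micrometres (> 0).
#' @param frame_interval Time between frames; minutes for transcription
#'   movies, seconds for clustering movies (> 0). Units are the caller's and
#'   are carried in `time_unit`.
#' @param time_unit Unit label for `frame_interval` (default `"min"`).
#' @param channel_name Free-text channel label.
#'
#' @return An object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(data, pixel_size_um, z_step_um = 1,
                             frame_interval = 1, time_unit = "min",
                             channel_name = "channel") {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, 1L, nrow(data), ncol(data)))
  } else if (length(dim(data)) == 3L) {
    d <- dim(data)
    data <- array(data, dim = c(d[1L], 1L, d[2L], d[3L]))
  }
  if (length(dim(data)) != 4L) {
    abort("`data` must be a matrix or a 3-D/4-D array (T x Z x Y x X).")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    abort("stack intensities must be finite.")
  }
  if (any(data < 0)) {
    abort("stack intensities must be nonnegative.")
  }
  for (nm in c("pixel_size_um", "z_step_um", "frame_interval")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(paste0("`", nm, "` must be a single positive finite number."))
    }
  }
  structure(
    list(
      data = data,
      pixel_size_um = pixel_size_um,
      z_step_um = z_step_um,
      frame_interval = frame_interval,
      time_unit = time_unit,
      channel_name = channel_name
    ),
    class = "calibrated_stack"
  )
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<calibrated_stack> %d frame(s) x %d slice(s) x %d x %d px [%s]\n",
    d[1], d[2], d[3], d[4], x$channel_name
  ))
  cat(sprintf(
    "  pixel %.4g um, z-step %.4g um, frame interval %.4g %s\n",
    x$pixel_size_um, x$z_step_um, x$frame_interval, x$time_unit
  ))
  invisible(x)
}

#' @export
dim.calibrated_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1L]
n_slices <- function(stack) dim(stack$data)[2L]

#' Extract one 2-D frame from a stack
#'
#' @param stack A [calibrated_stack()].
#' @param t Frame index (1-based).
#' @param z Slice index (1-based).
#' @return A `Y x X` numeric matrix.
#' @export
stack_frame <- function(stack, t = 1L, z = 1L) {
  d <- dim(stack$data)
  if (t < 1L || t > d[1L] || z < 1L || z > d[2L]) {
    abort("frame/slice index out of range.")
  }
  matrix(stack$data[t, z, , ], nrow = d[3L], ncol = d[4L])
}

#' Maximum-intensity projection over z
#'
#' @param stack A [calibrated_stack()].
#' @param t Frame index.
#' @return A `Y x X` matrix of per-pixel maxima over all slices.
#' @export
project_max <- function(stack, t = 1L) {
  d <- dim(stack$data)
  out <- stack_frame(stack, t, 1L)
  if (d[2L] > 1L) {
    for (z in 2L:d[2L]) out <- pmax(out, stack_frame(stack, t, z))
  }
  out
}

#' Sum-of-slices projection over a z range
#'
#' Per-pixel sum over `n_slices` consecutive focal planes, the projection used
#' before membrane and interface quantification.
#'
#' @param stack A [calibrated_stack()].
#' @param n_slices Number of slices to sum (from `z_start`).
#' @param t Frame index.
#' @param z_start First slice of the range (default 1).
#' @return A `Y x X` matrix.
#' @export
project_sum <- function(stack, n_slices = n_slices_available(stack), t = 1L,
                        z_start = 1L) {
  nz <- dim(stack$data)[2L]
  if (n_slices < 1L || z_start < 1L || z_start + n_slices - 1L > nz) {
    abort(sprintf(
      "slice range [%d, %d] outside available 1..%d.",
      z_start, z_start + n_slices - 1L, nz
    ))
  }
  out <- stack_frame(stack, t, z_start)
  if (n_slices > 1L) {
    for (z in (z_start + 1L):(z_start + n_slices - 1L)) {
      out <- out + stack_frame(stack, t, z)
    }
  }
  out
}

#' @rdname project_sum
#' @export
n_slices_available <- function(stack) dim(stack$data)[2L]

#' Frame acquisition times
#'
#' @param stack A [calibrated_stack()].
#' @param start Time of the first frame (same unit as `frame_interval`).
#' @return Numeric vector of length `T`.
#' @export
frame_times <- function(stack, start = 0) {
  start + (seq_len(n_frames(stack)) - 1L) * stack$frame_interval
}
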