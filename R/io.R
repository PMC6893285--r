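#' Write a calibrated stack to a multi-page TIFF
#'
#' Pages are written frame-major (`t1z1, t1z2, ..., t2z1, ...`). Pixel
#' values are stored as 16-bit counts (or 32-bit normalised floats) relative
#' to a recorded `intensity_scale`; with 16-bit storage, integer-valued data
#' not exceeding 65535 round-trip bit-exactly. Calibration and shape travel
#' in a JSON sidecar (`<path>.json`) so no information depends on TIFF tag
#' support.
#'
#' @param stack A [calibrated_stack()].
#' @param path Output TIFF path.
#' @param bits 16 (integer counts, default) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (!bits %in% c(16L, 32L)) abort("`bits` must be 16 or 32.")
  d <- dim(stack$data)
  mx <- max(stack$data)
  if (bits == 16L) {
    scale <- if (mx <= 65535) 1 else mx / 65535
  } else {
    scale <- if (mx > 0) mx else 1
  }
  pages <- vector("list", d[1L] * d[2L])
  i <- 0L
  for (t in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      i <- i + 1L
      img <- stack_frame(stack, t, z) / scale
      pages[[i]] <- if (bits == 16L) img / 65535 else img
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "LZW", reduce = FALSE)
  meta <- list(
    n_frames = d[1L], n_slices = d[2L], height = d[3L], width = d[4L],
    pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
    frame_interval = stack$frame_interval, time_unit = stack$time_unit,
    channel_name = stack$channel_name,
    intensity_scale = scale, bits = bits
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated stack from a multi-page TIFF
#'
#' Reads a TIFF written by [write_stack()] (JSON sidecar) or any multi-page
#' TIFF with calibration supplied as overrides. Page order is frame-major;
#' a plain 3-D file is interpreted as `T x Y x X` with a single z-slice
#' unless `n_slices` says otherwise. Missing calibration is an explicit
#' error, never a silent default.
#'
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um,frame_interval,time_unit,channel_name
#'   Calibration overrides; required (at least `pixel_size_um`) when no
#'   sidecar is present.
#' @param n_slices Number of z-slices per frame for files without a sidecar.
#' @return A [calibrated_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL,
                       frame_interval = NULL, time_unit = NULL,
                       channel_name = NULL, n_slices = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  pick <- function(override, key, default = NULL) {
    if (!is.null(override)) return(override)
    if (!is.null(meta[[key]])) return(meta[[key]])
    default
  }
  px <- pick(pixel_size_um, "pixel_size_um")
  if (is.null(px)) {
    abort("pixel size unknown: no sidecar metadata and no `pixel_size_um` override.")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- pick(NULL, "intensity_scale", 1)
  bits <- pick(NULL, "bits", 16L)
  nz <- as.integer(pick(n_slices, "n_slices", 1L))
  np <- length(pages)
  if (np %% nz != 0L) {
    abort(sprintf("%d pages do not divide into %d slice(s) per frame.", np, nz))
  }
  nt <- np %/% nz
  ny <- nrow(pages[[1L]])
  nx <- ncol(pages[[1L]])
  data <- array(0, dim = c(nt, nz, ny, nx))
  i <- 0L
  for (t in seq_len(nt)) {
    for (z in seq_len(nz)) {
      i <- i + 1L
      v <- pages[[i]]
      if (bits == 16L) v <- round(v * 65535)
      data[t, z, , ] <- v * scale
    }
  }
  calibrated_stack(
    data,
    pixel_size_um = px,
    z_step_um = pick(z_step_um, "z_step_um", 1),
    frame_interval = pick(frame_interval, "frame_interval", 1),
    time_unit = pick(time_unit, "time_unit", "min"),
    channel_name = pick(channel_name, "channel_name", "channel")
  )
}
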