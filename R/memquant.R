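#' Measure a membrane interface intensity profile
#'
#' Extracts an intensity profile along a line crossing a cell-cell
#' interface, averaging over a perpendicular width of `width_px` pixels
#' (bilinear interpolation at 1-px steps along the line). The dominant peak
#' of the lightly smoothed profile is located, and the raw profile is
#' integrated (trapezoidal rule) over a window of `w_int_um` micrometres
#' centred at the peak; the window is clipped to the profile support with a
#' flag if clipping occurs. A profile with no interior local maximum above
#' the prominence floor is flagged and reported with integral 0.
#'
#' @param image Numeric `Y x X` matrix (typically a [project_sum()]
#'   projection).
#' @param x0,y0,x1,y1 Line endpoints, 0-based pixel-centre coordinates.
#' @param pixel_size_um Pixel size, um.
#' @param width_px Averaging width perpendicular to the line (odd).
#' @param w_int_um Integration window, um (default 0.78).
#' @param smooth_sigma_px Gaussian s.d. for peak finding (profile samples).
#' @param min_prominence Minimum height of the peak above the profile
#'   minimum.
#' @param line_id,region Labels carried into the result.
#' @return A one-row tibble: `line_id`, `region`, `peak_um`,
#'   `peak_intensity`, `integrated_intensity`, `clipped`, `flagged`, and a
#'   `profile` list-column (tibble: `distance_um`, `intensity`).
#' @export
measure_interface <- function(image, x0, y0, x1, y1, pixel_size_um,
                              width_px = 7, w_int_um = 0.78,
                              smooth_sigma_px = 1, min_prominence = 0,
                              line_id = 1L, region = NA_character_) {
  check_scalar(pixel_size_um, "pixel_size_um", min = 0, allow_min = FALSE)
  check_scalar(w_int_um, "w_int_um", min = 0, allow_min = FALSE)
  if (width_px %% 2 == 0) abort("`width_px` must be odd.")
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len <= 0) abort("line endpoints coincide.")
  u <- c(x1 - x0, y1 - y0) / len
  nv <- c(-u[2L], u[1L])
  s <- seq(0, len, by = 1)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)

  interp <- function(x, y) {
    # bilinear, 0-based pixel centres; outside the image -> NA
    ny <- nrow(image)
    nx <- ncol(image)
    if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) return(NA_real_)
    ix <- floor(x)
    iy <- floor(y)
    fx <- x - ix
    fy <- y - iy
    ix2 <- min(ix + 1, nx - 1)
    iy2 <- min(iy + 1, ny - 1)
    (1 - fx) * (1 - fy) * image[iy + 1, ix + 1] +
      fx * (1 - fy) * image[iy + 1, ix2 + 1] +
      (1 - fx) * fy * image[iy2 + 1, ix + 1] +
      fx * fy * image[iy2 + 1, ix2 + 1]
  }
  prof <- vapply(s, function(si) {
    vals <- vapply(offs, function(o) {
      p <- c(x0, y0) + si * u + o * nv
      interp(p[1L], p[2L])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(prof)) abort("line (with its width) extends outside the image.")
  dist_um <- s * pixel_size_um

  smoothed <- if (length(prof) >= 3) {
    as.numeric(gaussian_filter(matrix(prof, nrow = 1), smooth_sigma_px))
  } else {
    prof
  }
  n <- length(prof)
  is_max <- rep(FALSE, n)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      is_max[i] <- smoothed[i] > smoothed[i - 1] && smoothed[i] >= smoothed[i + 1]
    }
  }
  flagged <- !any(is_max)
  peak_um <- NA_real_
  peak_intensity <- NA_real_
  integral <- 0
  clipped <- FALSE
  if (!flagged) {
    pk <- which(is_max)[which.max(smoothed[is_max])]
    if (smoothed[pk] - min(smoothed) <= min_prominence) {
      flagged <- TRUE
    } else {
      peak_um <- dist_um[pk]
      peak_intensity <- prof[pk]
      lo <- peak_um - w_int_um / 2
      hi <- peak_um + w_int_um / 2
      if (lo < min(dist_um) || hi > max(dist_um)) {
        clipped <- TRUE
        lo <- max(lo, min(dist_um))
        hi <- min(hi, max(dist_um))
      }
      xs <- sort(unique(c(lo, hi, dist_um[dist_um > lo & dist_um < hi])))
      ys <- stats::approx(dist_um, prof, xout = xs)$y
      integral <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
    }
  }
  tibble(
    line_id = line_id, region = region,
    peak_um = peak_um, peak_intensity = peak_intensity,
    integrated_intensity = integral,
    clipped = clipped, flagged = flagged,
    profile = list(tibble(distance_um = dist_um, intensity = prof))
  )
}

#' Measure many interfaces at once
#'
#' @param image Numeric matrix.
#' @param lines A data frame with columns `x0`, `y0`, `x1`, `y1` and
#'   optionally `line_id`, `region`, `embryo_id`.
#' @param ... Passed to [measure_interface()].
#' @return Row-bound [measure_interface()] results (plus `embryo_id` if
#'   provided).
#' @export
measure_interfaces <- function(image, lines, ...) {
  stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(lines)))
  ids <- if ("line_id" %in% names(lines)) lines$line_id else seq_len(nrow(lines))
  regions <- if ("region" %in% names(lines)) lines$region else NA_character_
  regions <- rep(regions, length.out = nrow(lines))
  out <- purrr::map(seq_len(nrow(lines)), function(i) {
    m <- measure_interface(image, lines$x0[i], lines$y0[i], lines$x1[i],
                           lines$y1[i], line_id = ids[i],
                           region = regions[i], ...)
    if ("embryo_id" %in% names(lines)) m$embryo_id <- lines$embryo_id[i]
    m
  })
  bind_rows(out)
}

#' Normalise measurements to a reference region
#'
#' Divides each value by the median of the reference-region values,
#' per embryo when an `embryo_id` column is present — e.g. interface
#' intensities normalised to the median value in the ectoderm of the same
#' embryo.
#'
#' @param measurements A data frame with a `region` column and the value
#'   column.
#' @param reference Reference region label.
#' @param value Name of the value column (default
#'   `"integrated_intensity"`).
#' @return `measurements` with an added `normalized_intensity` column.
#' @export
normalize_to_reference <- function(measurements, reference = "ectoderm",
                                   value = "integrated_intensity") {
  stopifnot("region" %in% names(measurements), value %in% names(measurements))
  grp <- if ("embryo_id" %in% names(measurements)) "embryo_id" else character(0)
  norm_one <- function(df) {
    ref <- df[[value]][df$region == reference & !is.na(df$region)]
    ref <- ref[is.finite(ref)]
    if (!length(ref)) {
      abort(paste0("no '", reference, "' measurements to normalise to."))
    }
    df$normalized_intensity <- df[[value]] / median(ref)
    df
  }
  if (length(grp)) {
    measurements %>%
      group_by(.data$embryo_id) %>%
      dplyr::group_modify(~ norm_one(.x)) %>%
      ungroup()
  } else {
    norm_one(measurements)
  }
}

#' Membrane-band and cytoplasm quantification per cell
#'
#' For each labelled cell, the membrane band is the set of its pixels within
#' `band_um` (converted to pixels) of the cell boundary — equivalently the
#' cell minus its erosion by that radius — and the cytoplasm is the
#' remaining interior. Reports the mean intensity of each compartment and
#' their cytoplasm-to-membrane ratio; cells too small to retain an interior
#' are flagged.
#'
#' @param image Numeric `Y x X` matrix.
#' @param cells Integer cell-label matrix aligned with `image`.
#' @param pixel_size_um Pixel size, um.
#' @param band_um Physical band thickness, um (default 0.3).
#' @param region Optional region-label matrix; each cell is tagged with its
#'   majority region (1 = "ectoderm", 2 = "mesoderm", other values kept as
#'   integers).
#' @return A tibble per cell: `cell`, `region` (if given), `n_band_px`,
#'   `n_interior_px`, `membrane_band_mean`, `cytoplasm_mean`,
#'   `cyt_to_mem_ratio`, `flagged`.
#' @export
membrane_band_quant <- function(image, cells, pixel_size_um, band_um = 0.3,
                                region = NULL) {
  if (!all(dim(image) == dim(cells))) {
    abort("`image` and `cells` must have the same shape.")
  }
  check_scalar(band_um, "band_um", min = 0, allow_min = FALSE)
  check_scalar(pixel_size_um, "pixel_size_um", min = 0, allow_min = FALSE)
  r_px <- round(band_um / pixel_size_um)
  interior <- label_interior_cpp(cells, r_px)
  labs <- sort(unique(as.integer(cells[cells > 0])))
  region_names <- c("ectoderm", "mesoderm")
  out <- purrr::map(labs, function(L) {
    in_cell <- cells == L
    band <- in_cell & !interior
    core <- in_cell & interior
    mem <- if (any(band)) mean(image[band]) else NA_real_
    cyt <- if (any(core)) mean(image[core]) else NA_real_
    reg <- NA_character_
    if (!is.null(region)) {
      rv <- as.integer(names(which.max(table(region[in_cell]))))
      reg <- if (rv %in% c(1L, 2L)) region_names[rv] else as.character(rv)
    }
    tibble(
      cell = L, region = reg,
      n_band_px = sum(band), n_interior_px = sum(core),
      membrane_band_mean = mem, cytoplasm_mean = cyt,
      cyt_to_mem_ratio = if (!is.na(mem) && !is.na(cyt) && mem > 0) {
        cyt / mem
      } else {
        NA_real_
      },
      flagged = !any(core)
    )
  })
  res <- bind_rows(out)
  if (is.null(region)) res$region <- NULL
  res
}

#' Two-channel particle colocalization by pixel overlap
#'
#' Detects particles independently in each channel (single-frame spot
#' calling) and classifies every channel-A particle by whether its segmented
#' mask shares at least one pixel with any channel-B particle mask.
#'
#' @param stack_a,stack_b Aligned single-frame [calibrated_stack()]s.
#' @param cfg A [spot_call_config()]; the defaults work for
#'   diffraction-limited vesicles.
#' @return A one-row tibble: `n_a`, `n_b`, `n_a_overlapping_b`,
#'   `percent_coloc` (= 100 * overlapping / n_a, `NA` when no A particle is
#'   found).
#' @export
coloc_percent <- function(stack_a, stack_b, cfg = spot_call_config()) {
  if (!all(dim(stack_a)[3:4] == dim(stack_b)[3:4])) {
    abort("channel stacks must be aligned (same frame dimensions).")
  }
  sa <- detect_spots(stack_a, cfg, frames = 1L, keep_masks = TRUE)
  sb <- detect_spots(stack_b, cfg, frames = 1L, keep_masks = TRUE)
  la <- attr(sa, "masks")[[1L]]
  lb <- attr(sb, "masks")[[1L]]
  n_a <- nrow(sa)
  n_b <- nrow(sb)
  hit <- 0L
  if (n_a > 0) {
    b_any <- lb > 0L
    overlap_labels <- unique(la[la > 0L & b_any])
    hit <- sum(sa$label %in% overlap_labels)
  }
  tibble(
    n_a = n_a, n_b = n_b, n_a_overlapping_b = hit,
    percent_coloc = if (n_a > 0) 100 * hit / n_a else NA_real_
  )
}
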