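#' Segment bright membrane clusters in a frame
#'
#' Connected components of pixels above a robust threshold: the median plus
#' `mad_mult` times the median absolute deviation (Gaussian-consistent) of
#' the positive pixels, so the segmentation is invariant under intensity
#' scaling. Components smaller than `min_size_px` are dropped. A flat frame
#' yields zero clusters.
#'
#' @param frame Numeric `Y x X` matrix.
#' @param mad_mult Threshold multiplier (default 3).
#' @param min_size_px Minimum component area, pixels.
#' @param connectivity 4 or 8.
#' @return Integer label matrix (0 = background).
#' @export
segment_clusters <- function(frame, mad_mult = 3, min_size_px = 3,
                             connectivity = 8L) {
  if (!is.matrix(frame) || !length(frame)) abort("`frame` must be a nonempty matrix.")
  pos <- frame[frame > 0]
  if (!length(pos)) {
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  thr <- median(pos) + mad_mult * stats::mad(pos, constant = 1.4826)
  labels <- label_components(frame > thr, connectivity)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    drop <- which(sizes < min_size_px)
    if (length(drop)) labels[labels %in% drop] <- 0L
  }
  labels
}

#' Clustering index of a frame
#'
#' The fraction of total image intensity residing in segmented clusters:
#' `(number of clusters x mean cluster intensity) / total image intensity`,
#' which reduces to the summed in-cluster intensity over the total. Bounded
#' by \[0, 1\] on nonnegative images and invariant under intensity scaling.
#'
#' @param frame Numeric matrix (nonnegative intensities).
#' @param clusters Label matrix from [segment_clusters()].
#' @return A single number in \[0, 1\], or `NA` (with a warning) when the
#'   frame's total intensity is not positive.
#' @export
clustering_index <- function(frame, clusters) {
  total <- sum(frame)
  if (!is.finite(total) || total <= 0) {
    warn("total image intensity is not positive; clustering index undefined.")
    return(NA_real_)
  }
  sum(frame[clusters > 0L]) / total
}

#' Per-frame cluster statistics for a movie
#'
#' @param stack A [calibrated_stack()] (single z-slice; seconds time base
#'   for clustering movies).
#' @param mad_mult,min_size_px,connectivity Passed to [segment_clusters()].
#' @return A tibble of class `cluster_series`: `frame`, `t`, `n_clusters`,
#'   `mean_cluster_intensity`, `total_image_intensity`, `clustering_index`.
#' @export
cluster_series <- function(stack, mad_mult = 3, min_size_px = 3,
                           connectivity = 8L) {
  stopifnot(inherits(stack, "calibrated_stack"))
  times <- frame_times(stack)
  nt <- n_frames(stack)
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    img <- stack_frame(stack, t, 1L)
    labels <- segment_clusters(img, mad_mult, min_size_px, connectivity)
    n_cl <- max(labels)
    feats <- extract_spot_intensity(labels, img)
    out[[t]] <- tibble(
      frame = t, t = times[t],
      n_clusters = n_cl,
      mean_cluster_intensity = if (n_cl > 0) {
        mean(feats$integrated_intensity)
      } else {
        NA_real_
      },
      total_image_intensity = sum(img),
      clustering_index = clustering_index(img, labels)
    )
  }
  res <- bind_rows(out)
  class(res) <- c("cluster_series", class(res))
  res
}

#' Half-time of exponential cluster growth
#'
#' Fits `index(t) = P * (1 - 2^(-t / t_half))` to a clustering-index time
#' series by least squares, using a deterministic multi-start (log-spaced
#' half-times) polished with Levenberg-Marquardt.
#'
#' @param series A [cluster_series()] tibble (needs `t` and
#'   `clustering_index`), with at least 5 frames spanning the rise.
#' @return An object of class `half_time_fit`: `t_half` (same unit as `t`),
#'   `plateau`, `rss`, `converged`, and the series. A flat or empty series
#'   is flagged `converged = FALSE`.
#' @export
estimate_half_time <- function(series) {
  stopifnot(all(c("t", "clustering_index") %in% names(series)))
  keep <- is.finite(series$clustering_index)
  t <- series$t[keep]
  y <- series$clustering_index[keep]
  if (length(t) < 5L) abort("need at least 5 usable frames.")
  out <- list(t_half = NA_real_, plateau = NA_real_, rss = NA_real_,
              converged = FALSE, series = series)
  class(out) <- "half_time_fit"
  if (max(y) <= 0 || stats::var(y) == 0) {
    return(out)
  }
  rss_fun <- function(par) {
    sum((y - exp(par[2L]) * (1 - 2^(-t / exp(par[1L]))))^2)
  }
  span <- diff(range(t))
  starts <- log(span * c(0.02, 0.05, 0.1, 0.25, 0.5, 1, 2))
  p0 <- log(max(y))
  best <- NULL
  for (s in starts) {
    o <- optim(c(s, p0), rss_fun, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  polished <- tryCatch({
    fit <- minpack.lm::nls.lm(
      par = list(lth = best$par[1L], lp = best$par[2L]),
      fn = function(p) y - exp(p$lp) * (1 - 2^(-t / exp(p$lth))),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    p <- coef(fit)
    if (rss_fun(c(p[["lth"]], p[["lp"]])) <= best$value) {
      c(p[["lth"]], p[["lp"]])
    } else {
      best$par
    }
  }, error = function(e) best$par)
  t_half <- exp(polished[1L])
  # a half-time pinned far outside the observation window is not a real rise
  if (!is.finite(t_half) || t_half > 100 * span) {
    return(out)
  }
  out$t_half <- t_half
  out$plateau <- exp(polished[2L])
  out$rss <- rss_fun(polished)
  out$converged <- TRUE
  out
}

#' @export
print.half_time_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<half_time_fit> t_half = %.4g, plateau = %.4g (rss = %.3g)\n",
                x$t_half, x$plateau, x$rss))
  } else {
    cat("<half_time_fit> not converged (flat or non-rising series)\n")
  }
  invisible(x)
}

#' @export
tidy.half_time_fit <- function(x, ...) {
  tibble(term = c("t_half", "plateau"), estimate = c(x$t_half, x$plateau))
}

#' @export
glance.half_time_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged,
         n_frames = sum(is.finite(x$series$clustering_index)))
}
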