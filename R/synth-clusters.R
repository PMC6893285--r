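#' Parameters for the membrane-clustering movie generator
#'
#' Emulates light-induced redistribution of a membrane protein into clusters:
#' a square cell lattice carries a fixed total signal mass, of which a
#' fraction `f(t) = f_max * (1 - 2^(-t / half_time_s))` sits in small
#' clusters at fixed membrane sites at time `t`, with the remainder spread
#' uniformly over the membrane. Total intensity is conserved exactly in every
#' frame when `noise_model = "none"`. The default half-time of 40 s matches
#' the clustering kinetics the generator emulates; the 2-s frame interval and
#' 6-min duration match a typical acquisition.
#'
#' @param duration_s,frame_interval_s Movie length and frame spacing, s.
#' @param half_time_s Half-time of the clustered fraction, s (> 0).
#' @param f_max Plateau clustered fraction, in (0, 1].
#' @param total_intensity Conserved per-frame photon sum.
#' @param n_cells_x,n_cells_y,cell_size_px Lattice geometry.
#' @param membrane_width_px Thickness of the membrane lines, pixels.
#' @param n_cluster_sites Number of cluster sites on the membrane.
#' @param cluster_radius_px Radius of each cluster disk, pixels.
#' @param noise_model,noise_scale As in [spot_movie_params()].
#' @param seed Integer seed.
#' @return A validated parameter list of class `cluster_movie_params`.
#' @export
cluster_movie_params <- function(duration_s = 360, frame_interval_s = 2,
                                 half_time_s = 40, f_max = 0.8,
                                 total_intensity = 1e6,
                                 n_cells_x = 6, n_cells_y = 6,
                                 cell_size_px = 24, membrane_width_px = 2,
                                 n_cluster_sites = 10, cluster_radius_px = 1,
                                 noise_model = c("none", "gaussian", "poisson"),
                                 noise_scale = 0, seed = NULL) {
  p <- list(
    duration_s = check_scalar(duration_s, "duration_s", min = 0),
    frame_interval_s = check_scalar(frame_interval_s, "frame_interval_s", min = 0, allow_min = FALSE),
    half_time_s = check_scalar(half_time_s, "half_time_s", min = 0, allow_min = FALSE),
    f_max = check_scalar(f_max, "f_max", min = 0, max = 1, allow_min = FALSE),
    total_intensity = check_scalar(total_intensity, "total_intensity", min = 0, allow_min = FALSE),
    n_cells_x = check_scalar(n_cells_x, "n_cells_x", min = 1),
    n_cells_y = check_scalar(n_cells_y, "n_cells_y", min = 1),
    cell_size_px = check_scalar(cell_size_px, "cell_size_px", min = 4),
    membrane_width_px = check_scalar(membrane_width_px, "membrane_width_px", min = 1),
    n_cluster_sites = check_scalar(n_cluster_sites, "n_cluster_sites", min = 1),
    cluster_radius_px = check_scalar(cluster_radius_px, "cluster_radius_px", min = 0),
    noise_model = match.arg(noise_model),
    noise_scale = check_scalar(noise_scale, "noise_scale", min = 0),
    seed = seed
  )
  structure(p, class = "cluster_movie_params")
}

membrane_lattice_mask <- function(n_cells_y, n_cells_x, cell_size_px,
                                  width_px) {
  ny <- n_cells_y * cell_size_px + 1L
  nx <- n_cells_x * cell_size_px + 1L
  yy <- matrix(seq_len(ny) - 1L, ny, nx)
  xx <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  dy <- abs(yy - round(yy / cell_size_px) * cell_size_px)
  dx <- abs(xx - round(xx / cell_size_px) * cell_size_px)
  d <- pmin(dy, dx)
  list(mask = d <= (width_px - 1) / 2, dist = d, ny = ny, nx = nx)
}

#' Generate a synthetic membrane-clustering movie
#'
#' @param params A [cluster_movie_params()] object.
#' @return A list with `stack` (a [calibrated_stack()], seconds time base)
#'   and `truth` containing `f_series` (tibble: `frame`, `t_s`, `f`),
#'   `cluster_mask`, `membrane_mask`, and `params`.
#' @export
gen_cluster_movie <- function(params) {
  stopifnot(inherits(params, "cluster_movie_params"))
  p <- params
  with_seed(p$seed, {
    lat <- membrane_lattice_mask(p$n_cells_y, p$n_cells_x, p$cell_size_px,
                                 p$membrane_width_px)
    mem_idx <- which(lat$mask)
    # cluster sites: greedy pick of membrane pixels with a minimum spacing
    min_sep <- 2 * (p$cluster_radius_px + 2)
    cand <- sample(mem_idx)
    sites <- integer(0)
    site_yx <- matrix(numeric(0), ncol = 2)
    for (i in cand) {
      y <- (i - 1) %% lat$ny
      x <- (i - 1) %/% lat$ny
      if (nrow(site_yx) == 0 ||
          all((site_yx[, 1] - y)^2 + (site_yx[, 2] - x)^2 >= min_sep^2)) {
        sites <- c(sites, i)
        site_yx <- rbind(site_yx, c(y, x))
      }
      if (length(sites) >= p$n_cluster_sites) break
    }
    if (length(sites) < p$n_cluster_sites) {
      abort("could not place the requested number of cluster sites; reduce `n_cluster_sites` or enlarge the lattice.")
    }
    cl_mask <- matrix(FALSE, lat$ny, lat$nx)
    r <- p$cluster_radius_px
    for (s in seq_len(nrow(site_yx))) {
      ys <- max(0, site_yx[s, 1] - ceiling(r)):min(lat$ny - 1, site_yx[s, 1] + ceiling(r))
      xs <- max(0, site_yx[s, 2] - ceiling(r)):min(lat$nx - 1, site_yx[s, 2] + ceiling(r))
      for (y in ys) for (x in xs) {
        if ((y - site_yx[s, 1])^2 + (x - site_yx[s, 2])^2 <= r^2) {
          cl_mask[y + 1, x + 1] <- TRUE
        }
      }
    }
    n_mem <- length(mem_idx)
    n_cl <- sum(cl_mask)

    times <- seq(0, p$duration_s, by = p$frame_interval_s)
    f <- p$f_max * (1 - 2^(-times / p$half_time_s))
    nt <- length(times)
    data <- array(0, dim = c(nt, 1L, lat$ny, lat$nx))
    for (t in seq_len(nt)) {
      img <- matrix(0, lat$ny, lat$nx)
      img[mem_idx] <- (1 - f[t]) * p$total_intensity / n_mem
      img[cl_mask] <- img[cl_mask] + f[t] * p$total_intensity / n_cl
      data[t, 1L, , ] <- apply_noise(img, p$noise_model, p$noise_scale)
    }
    stack <- calibrated_stack(
      data, pixel_size_um = 0.13, frame_interval = p$frame_interval_s,
      time_unit = "s", channel_name = "Delta-GFP-CRY2"
    )
    list(
      stack = stack,
      truth = list(
        f_series = tibble(frame = seq_len(nt), t_s = times, f = f),
        cluster_mask = cl_mask,
        membrane_mask = lat$mask,
        params = p
      )
    )
  })
}
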