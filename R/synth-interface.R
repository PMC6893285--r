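#' Generate a synthetic cell lattice with region-dependent membrane levels
#'
#' Renders a square cell lattice whose edges are ridges with a Gaussian
#' cross-section, split into two regions: a reference region ("ectoderm", the
#' left half) at full membrane amplitude, and a depleted region ("mesoderm",
#' the right half) whose ridge amplitude is `depletion_factor` times the
#' reference. The default `depletion_factor = 0.3` emulates a membrane pool
#' depleted by ~70% relative to the reference. A flat per-region cytoplasm
#' level is added everywhere.
#'
#' @param n_cells_x,n_cells_y,cell_size_px Lattice geometry (cells per side
#'   and cell edge length in pixels). `n_cells_x` should be even so the two
#'   regions hold whole cells.
#' @param membrane_amplitude Ridge peak amplitude in the reference region.
#' @param cytoplasm_level Flat interior level; a single value or
#'   `c(ectoderm, mesoderm)`.
#' @param ridge_sigma_um Gaussian cross-section s.d. of the ridge, um.
#' @param depletion_factor Mesoderm/ectoderm ridge amplitude ratio, in
#'   (0, 1].
#' @param pixel_size_um Pixel size, um.
#' @param noise_model,noise_scale As in [spot_movie_params()].
#' @param seed Integer seed (only noise is stochastic).
#'
#' @return A list with `stack` (single-frame [calibrated_stack()]), `labels`
#'   (list: `cells` integer matrix of per-cell labels, `region` integer
#'   matrix with 1 = ectoderm / 2 = mesoderm, `skeleton` logical membrane
#'   skeleton), and `truth` (per-region ridge amplitudes and cytoplasm
#'   levels, `ridge_sigma_px`, `boundary_x_px`, distance map `dist_px`, and
#'   `params`).
#' @export
gen_interface_image <- function(n_cells_x = 10, n_cells_y = 6,
                                cell_size_px = 30, membrane_amplitude = 200,
                                cytoplasm_level = 2, ridge_sigma_um = 0.15,
                                depletion_factor = 0.3, pixel_size_um = 0.1,
                                noise_model = c("none", "gaussian", "poisson"),
                                noise_scale = 0, seed = NULL) {
  check_scalar(n_cells_x, "n_cells_x", min = 2)
  check_scalar(n_cells_y, "n_cells_y", min = 1)
  check_scalar(cell_size_px, "cell_size_px", min = 4)
  check_scalar(membrane_amplitude, "membrane_amplitude", min = 0)
  check_scalar(ridge_sigma_um, "ridge_sigma_um", min = 0, allow_min = FALSE)
  check_scalar(depletion_factor, "depletion_factor", min = 0, max = 1,
               allow_min = FALSE)
  check_scalar(pixel_size_um, "pixel_size_um", min = 0, allow_min = FALSE)
  noise_model <- match.arg(noise_model)
  cyt <- rep(cytoplasm_level, length.out = 2L)
  if (any(!is.finite(cyt)) || any(cyt < 0)) {
    abort("`cytoplasm_level` must be nonnegative and finite.")
  }

  ny <- n_cells_y * cell_size_px + 1L
  nx <- n_cells_x * cell_size_px + 1L
  y0 <- matrix(seq_len(ny) - 1L, ny, nx)
  x0 <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
  dy <- abs(y0 - round(y0 / cell_size_px) * cell_size_px)
  dx <- abs(x0 - round(x0 / cell_size_px) * cell_size_px)
  d <- pmin(dy, dx)

  boundary_x <- (n_cells_x %/% 2) * cell_size_px
  region <- matrix(1L, ny, nx)
  region[x0 >= boundary_x] <- 2L
  sigma_px <- ridge_sigma_um / pixel_size_um
  amp <- c(membrane_amplitude, membrane_amplitude * depletion_factor)

  img <- cyt[region] + amp[region] * exp(-d^2 / (2 * sigma_px^2))
  img <- matrix(img, ny, nx)
  with_seed(seed, {
    img <- apply_noise(img, noise_model, noise_scale)
  })

  cell_col <- pmin(x0 %/% cell_size_px, n_cells_x - 1L)
  cell_row <- pmin(y0 %/% cell_size_px, n_cells_y - 1L)
  cells <- matrix(as.integer(cell_row * n_cells_x + cell_col + 1L), ny, nx)

  stack <- calibrated_stack(img, pixel_size_um = pixel_size_um,
                            channel_name = "membrane")
  list(
    stack = stack,
    labels = list(
      cells = cells,
      region = region,
      skeleton = d <= 0.5
    ),
    truth = list(
      ridge_amplitude = c(ectoderm = amp[1], mesoderm = amp[2]),
      cytoplasm_level = c(ectoderm = cyt[1], mesoderm = cyt[2]),
      ridge_sigma_px = sigma_px,
      boundary_x_px = boundary_x,
      dist_px = d,
      params = list(
        n_cells_x = n_cells_x, n_cells_y = n_cells_y,
        cell_size_px = cell_size_px, membrane_amplitude = membrane_amplitude,
        cytoplasm_level = cyt, ridge_sigma_um = ridge_sigma_um,
        depletion_factor = depletion_factor, pixel_size_um = pixel_size_um,
        noise_model = noise_model, noise_scale = noise_scale, seed = seed
      )
    )
  )
}
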