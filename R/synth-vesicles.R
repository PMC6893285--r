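#' Generate a two-channel vesicle field with a set overlap fraction
#'
#' Channel A holds `n_vesicles` diffraction-limited vesicles. Each A vesicle
#' independently receives a channel-B partner with probability
#' `overlap_fraction`; partnered B vesicles are placed so their pixel disks
#' share at least one pixel with the A vesicle, while unpartnered B vesicles
#' are placed far from every A vesicle so no detected masks can touch. The
#' realized overlap indicator is recorded per vesicle from the actual pixel
#' masks, so a colocalization estimator can be checked against exact
#' bookkeeping.
#'
#' @param n_vesicles Number of channel-A vesicles.
#' @param overlap_fraction Probability of a pixel-overlapping B partner, in
#'   \[0, 1\].
#' @param vesicle_radius_px Ground-truth vesicle disk radius, pixels. Spots
#'   are rendered as Gaussians with sigma `vesicle_radius_px / 1.5`.
#' @param frame_px Square frame side length, pixels.
#' @param amplitude,background Rendering intensities.
#' @param min_separation_px Minimum A-A centre distance.
#' @param clear_px Minimum distance of an unpartnered B vesicle from every A
#'   centre; must exceed twice the expected detection mask radius.
#' @param noise_model,noise_scale As in [spot_movie_params()].
#' @param seed Integer seed.
#'
#' @return A list with `stack_a`, `stack_b` (single-frame
#'   [calibrated_stack()]s), and `truth`: `vesicles` tibble (`id`, `x_px`,
#'   `y_px`, `partner` drawn indicator, `overlaps` realized pixel-overlap
#'   indicator, partner coordinates), `mask_a`, `mask_b` ground-truth disk
#'   masks, and `params`.
#' @export
gen_vesicle_field <- function(n_vesicles = 200, overlap_fraction = 0.75,
                              vesicle_radius_px = 3, frame_px = 512,
                              amplitude = 1000, background = 50,
                              min_separation_px = 20, clear_px = 16,
                              noise_model = c("none", "gaussian", "poisson"),
                              noise_scale = 0, seed = NULL) {
  check_scalar(n_vesicles, "n_vesicles", min = 1)
  check_scalar(overlap_fraction, "overlap_fraction", min = 0, max = 1)
  check_scalar(vesicle_radius_px, "vesicle_radius_px", min = 1)
  check_scalar(frame_px, "frame_px", min = 64)
  noise_model <- match.arg(noise_model)
  # crude packing bound before attempting placement
  if (n_vesicles * (min_separation_px / 2)^2 * pi > 0.7 * frame_px^2) {
    abort("too many vesicles for the frame at this separation; enlarge `frame_px` or reduce `n_vesicles`.")
  }

  with_seed(seed, {
    margin <- clear_px + vesicle_radius_px + 2
    place_points <- function(n, min_dist, avoid = NULL, avoid_dist = 0) {
      pts <- matrix(numeric(0), ncol = 2)
      tries <- 0L
      while (nrow(pts) < n) {
        tries <- tries + 1L
        if (tries > 200000L) {
          abort("vesicle placement failed; the field is too crowded.")
        }
        cand <- runif(2, min = margin, max = frame_px - 1 - margin)
        ok <- TRUE
        if (nrow(pts) > 0 &&
            min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) < min_dist^2) {
          ok <- FALSE
        }
        if (ok && !is.null(avoid) && nrow(avoid) > 0 &&
            min((avoid[, 1] - cand[1])^2 + (avoid[, 2] - cand[2])^2) < avoid_dist^2) {
          ok <- FALSE
        }
        if (ok) pts <- rbind(pts, cand)
      }
      pts
    }

    a <- place_points(n_vesicles, min_separation_px)
    partner <- runif(n_vesicles) < overlap_fraction
    r <- vesicle_radius_px

    b <- matrix(NA_real_, n_vesicles, 2)
    if (any(partner)) {
      th <- runif(sum(partner), 0, 2 * pi)
      # centre offset r guarantees disks of radius r share pixels
      b[partner, ] <- a[partner, , drop = FALSE] +
        r * cbind(cos(th), sin(th))
    }
    n_free <- sum(!partner)
    if (n_free > 0) {
      b[!partner, ] <- place_points(n_free, min_dist = 2 * r + 2,
                                    avoid = a, avoid_dist = clear_px)
    }

    disk_mask <- function(centres) {
      m <- matrix(FALSE, frame_px, frame_px)
      for (i in seq_len(nrow(centres))) {
        cy <- centres[i, 2]
        cx <- centres[i, 1]
        ys <- max(0, floor(cy - r)):min(frame_px - 1, ceiling(cy + r))
        xs <- max(0, floor(cx - r)):min(frame_px - 1, ceiling(cx + r))
        for (y in ys) for (x in xs) {
          if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y + 1, x + 1] <- TRUE
        }
      }
      m
    }
    mask_a <- disk_mask(a)
    mask_b <- disk_mask(b)

    # realized pixel overlap per A vesicle, from the actual masks
    overlaps <- vapply(seq_len(n_vesicles), function(i) {
      cy <- a[i, 2]
      cx <- a[i, 1]
      ys <- max(0, floor(cy - r)):min(frame_px - 1, ceiling(cy + r))
      xs <- max(0, floor(cx - r)):min(frame_px - 1, ceiling(cx + r))
      hit <- FALSE
      for (y in ys) {
        for (x in xs) {
          if ((y - cy)^2 + (x - cx)^2 <= r^2 && mask_b[y + 1, x + 1]) {
            hit <- TRUE
            break
          }
        }
        if (hit) break
      }
      hit
    }, logical(1))

    render <- function(centres) {
      img <- matrix(background, frame_px, frame_px)
      for (i in seq_len(nrow(centres))) {
        img <- add_gaussian_spot(img, centres[i, 1], centres[i, 2],
                                 amplitude, r / 1.5)
      }
      apply_noise(img, noise_model, noise_scale)
    }
    stack_a <- calibrated_stack(render(a), pixel_size_um = 0.13,
                                channel_name = "Delta")
    stack_b <- calibrated_stack(render(b), pixel_size_um = 0.13,
                                channel_name = "Rab5")

    list(
      stack_a = stack_a,
      stack_b = stack_b,
      truth = list(
        vesicles = tibble(
          id = seq_len(n_vesicles),
          x_px = a[, 1], y_px = a[, 2],
          partner = partner,
          overlaps = overlaps,
          partner_x_px = b[, 1], partner_y_px = b[, 2]
        ),
        mask_a = mask_a,
        mask_b = mask_b,
        params = list(
          n_vesicles = n_vesicles, overlap_fraction = overlap_fraction,
          vesicle_radius_px = vesicle_radius_px, frame_px = frame_px,
          amplitude = amplitude, background = background,
          min_separation_px = min_separation_px, clear_px = clear_px,
          noise_model = noise_model, noise_scale = noise_scale, seed = seed
        )
      )
    )
  })
}
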