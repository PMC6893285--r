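#' Generate a mosaic tissue with a clone mask and biased SOP placement
#'
#' Emulates a mosaic epithelium containing a mutant clone (left half of the
#' tissue) and proneural clusters straddling the clone boundary. Each
#' boundary cluster resolves to a single sensory organ precursor (SOP) that
#' falls on the clone side with probability
#' `exp(bias_beta) / (1 + exp(bias_beta))`; `bias_beta = 0` reproduces the
#' unbiased 50:50 null. Additional clusters can be placed deep inside and
#' outside the clone, away from the boundary.
#'
#' @param width_px,height_px Tissue size, pixels.
#' @param n_border_clusters Number of boundary-straddling proneural
#'   clusters.
#' @param n_interior_clusters Clusters placed far from the boundary (half
#'   inside, half outside).
#' @param cluster_radius_px Proneural cluster radius; SOPs fall within this
#'   distance of the boundary, and it is the natural border band for
#'   scoring.
#' @param bias_beta Log-odds of an SOP resolving inside the clone. Values
#'   beyond +/- 40 saturate to certainty.
#' @param seed Integer seed.
#'
#' @return A list with `clone_mask` (logical matrix, `TRUE` inside the
#'   clone), `sops` tibble (`sop_id`, `cluster_id`, `x_px`, `y_px`,
#'   `at_border`, `inside` ground-truth side), and `truth` (per-cluster
#'   outcomes and `params`).
#' @export
gen_clone_tissue <- function(width_px = 400, height_px = 400,
                             n_border_clusters = 50,
                             n_interior_clusters = 0,
                             cluster_radius_px = 8, bias_beta = 0,
                             seed = NULL) {
  check_scalar(width_px, "width_px", min = 32)
  check_scalar(height_px, "height_px", min = 32)
  check_scalar(n_border_clusters, "n_border_clusters", min = 0)
  check_scalar(n_interior_clusters, "n_interior_clusters", min = 0)
  check_scalar(cluster_radius_px, "cluster_radius_px", min = 1)
  if (!is.numeric(bias_beta) || length(bias_beta) != 1L || is.na(bias_beta)) {
    abort("`bias_beta` must be a single finite number (infinities are capped).")
  }
  beta <- max(min(bias_beta, 40), -40)

  with_seed(seed, {
    boundary_x <- width_px / 2
    clone_mask <- matrix(FALSE, height_px, width_px)
    clone_mask[, seq_len(floor(boundary_x))] <- TRUE
    r <- cluster_radius_px
    p_inside <- plogis(beta)

    nb <- as.integer(n_border_clusters)
    border <- tibble(
      cluster_id = seq_len(nb),
      y_px = runif(nb, r + 1, height_px - r - 2),
      # clone side is x < boundary_x; keep the SOP a clear half-pixel off
      # the boundary so rounding cannot flip its side
      inside = runif(nb) < p_inside,
      at_border = TRUE
    )
    # offsets stay at least 0.6 px clear of the discrete boundary-pixel
    # centres on both ends so a band of one cluster radius always holds them
    border$x_px <- ifelse(border$inside,
                          boundary_x - runif(nb, 0.6, max(r - 0.6, 0.7)),
                          boundary_x + runif(nb, 0.6, max(r - 0.6, 0.7)))
    ni <- as.integer(n_interior_clusters)
    interior <- tibble(
      cluster_id = nb + seq_len(ni),
      y_px = runif(ni, r + 1, height_px - r - 2),
      inside = seq_len(ni) %% 2L == 0L,
      at_border = FALSE
    )
    depth <- 4 * r
    interior$x_px <- ifelse(interior$inside,
                            runif(ni, depth, boundary_x - depth),
                            runif(ni, boundary_x + depth, width_px - depth))
    sops <- bind_rows(border, interior) %>%
      mutate(sop_id = dplyr::row_number()) %>%
      select("sop_id", "cluster_id", "x_px", "y_px", "at_border", "inside")

    list(
      clone_mask = clone_mask,
      sops = sops,
      truth = list(
        boundary_x_px = boundary_x,
        p_inside = p_inside,
        params = list(
          width_px = width_px, height_px = height_px,
          n_border_clusters = n_border_clusters,
          n_interior_clusters = n_interior_clusters,
          cluster_radius_px = cluster_radius_px,
          bias_beta = bias_beta, seed = seed
        )
      )
    )
  })
}
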