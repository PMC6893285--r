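#' Pipeline configuration
#'
#' Bundles per-stage parameters, a master seed, and an output directory.
#' Each stochastic stage receives a fixed sub-seed derived from the master
#' seed (`seed + stage offset`), so one seed governs the whole run and
#' repeated runs are byte-identical. The configuration hash is recorded in
#' every output.
#'
#' @param seed Master integer seed.
#' @param out_dir Output directory (created on demand).
#' @param spot_movie A [spot_movie_params()] (its `seed` is overridden).
#' @param spot_call A [spot_call_config()].
#' @param cluster_movie A [cluster_movie_params()] (seed overridden).
#' @param interface,vesicles,clones Named lists of overrides for
#'   [gen_interface_image()], [gen_vesicle_field()], [gen_clone_tissue()].
#' @param n_max_nuclei Plateau constant for the activation fit; defaults to
#'   the generator's nucleus count.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("optonotch-run-"),
                            spot_movie = spot_movie_params(),
                            spot_call = spot_call_config(),
                            cluster_movie = cluster_movie_params(),
                            interface = list(), vesicles = list(),
                            clones = list(), n_max_nuclei = NULL) {
  check_scalar(seed, "seed")
  spot_movie$seed <- seed + 101
  cluster_movie$seed <- seed + 202
  interface$seed <- seed + 303
  vesicles$seed <- seed + 404
  clones$seed <- seed + 505
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    spot_movie = spot_movie, spot_call = spot_call,
    cluster_movie = cluster_movie, interface = interface,
    vesicles = vesicles, clones = clones, n_max_nuclei = n_max_nuclei
  )
  cfg$config_hash <- hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; stage entries
#' are named parameter lists merged over the defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    seed = y$seed %||% 1L,
    out_dir = y$out_dir %||% tempfile("optonotch-run-")
  )
  if (!is.null(y$spot_movie)) {
    args$spot_movie <- do.call(spot_movie_params, y$spot_movie)
  }
  if (!is.null(y$spot_call)) {
    args$spot_call <- do.call(spot_call_config, y$spot_call)
  }
  if (!is.null(y$cluster_movie)) {
    args$cluster_movie <- do.call(cluster_movie_params, y$cluster_movie)
  }
  for (nm in c("interface", "vesicles", "clones")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$n_max_nuclei)) args$n_max_nuclei <- y$n_max_nuclei
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic inputs:
#' `spots` (movie generation + spot calling), `kinetics` (activation curve
#' and fit; requires `spots`), `clusters` (clustering movie, index series,
#' half-time), `membrane` (interface image, per-cell band quantification),
#' `coloc` (vesicle field, colocalization), `clones` (mosaic tissue, border
#' tally). Requesting a stage without its dependency skips it with a
#' warning. Results are returned and, if `write = TRUE`, written as CSV
#' tables plus a JSON summary carrying the seed and configuration hash.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("spots", "kinetics", "clusters", "membrane", "coloc", "clones")`.
#' @param write Write CSV/JSON outputs to `config$out_dir`?
#' @return A named list of stage results (class `pipeline_result`).
#' @export
run_pipeline <- function(config, stages = c("spots", "kinetics", "clusters",
                                            "membrane", "coloc", "clones"),
                         write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list(seed = config$seed, config_hash = config$config_hash)

  if ("kinetics" %in% stages && !"spots" %in% stages) {
    warn("stage 'kinetics' requires 'spots'; skipping it.")
    stages <- setdiff(stages, "kinetics")
  }

  if ("spots" %in% stages) {
    movie <- gen_spot_movie(config$spot_movie)
    spots <- detect_spots(movie$stack, config$spot_call)
    res$spots <- spots
    res$spot_truth <- movie$truth
    if ("kinetics" %in% stages) {
      n_max <- config$n_max_nuclei %||% nrow(movie$truth$nuclei)
      curve <- build_activation_curve(
        spots, movie$truth$region_length_um, movie$truth$times,
        embryo_id = "synthetic-1", condition = "control"
      )
      fit <- fit_activation(curve, n_max / movie$truth$region_length_um)
      res$curve <- curve
      res$fit <- fit
    }
  }
  if ("clusters" %in% stages) {
    cl <- gen_cluster_movie(config$cluster_movie)
    series <- cluster_series(cl$stack)
    res$cluster_series <- series
    res$half_time <- estimate_half_time(series)
  }
  if ("membrane" %in% stages) {
    iface <- do.call(gen_interface_image, config$interface)
    res$membrane <- membrane_band_quant(
      stack_frame(iface$stack), iface$labels$cells,
      pixel_size_um = iface$stack$pixel_size_um, region = iface$labels$region
    )
  }
  if ("coloc" %in% stages) {
    field <- do.call(gen_vesicle_field, config$vesicles)
    res$coloc <- coloc_percent(field$stack_a, field$stack_b, config$spot_call)
    res$coloc_truth_percent <- 100 * mean(field$truth$vesicles$overlaps)
  }
  if ("clones" %in% stages) {
    tissue <- do.call(gen_clone_tissue, config$clones)
    band <- tissue$truth$params$cluster_radius_px
    res$clone_tally <- score_border_sops(
      tissue$clone_mask, tissue$sops, border_band_px = band,
      pupa_id = 1L, condition = "simulated"
    )
  }
  class(res) <- "pipeline_result"
  if (write) write_report(res, config$out_dir)
  res
}

#' Write pipeline results as CSV tables, a JSON summary, and plots
#'
#' Every numeric value in the JSON summary also appears in a CSV table;
#' plots are regeneration artifacts derived from the tables, never inputs.
#'
#' @param results A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    df$config_hash <- results$config_hash
    readr::write_csv(df, file.path(dir, name))
  }
  summary <- list(seed = results$seed, config_hash = results$config_hash)
  if (!is.null(results$spots)) {
    wr(results$spots, "spots.csv")
    summary$n_spots <- nrow(results$spots)
  }
  if (!is.null(results$curve)) {
    wr(results$curve, "curves.csv")
    if (results$fit$converged) {
      wr(tibble(k = results$fit$k, t0 = results$fit$t0,
                n_max = results$fit$n_max, rss = results$fit$rss),
         "fits.csv")
      summary$activation_rate_k <- results$fit$k
      summary$onset_delay_t0 <- results$fit$t0
    }
    p <- autoplot(results$fit)
    ggsave(file.path(dir, "activation_fit.pdf"), p, width = 6, height = 4)
  }
  if (!is.null(results$cluster_series)) {
    wr(results$cluster_series, "clusters.csv")
    if (results$half_time$converged) {
      summary$cluster_t_half <- results$half_time$t_half
      wr(tidy(results$half_time), "cluster_fit.csv")
    }
    ggsave(file.path(dir, "cluster_series.pdf"),
           autoplot(results$cluster_series), width = 6, height = 4)
  }
  if (!is.null(results$membrane)) {
    wr(results$membrane, "interfaces.csv")
    if ("region" %in% names(results$membrane)) {
      by_reg <- results$membrane %>%
        group_by(.data$region) %>%
        summarise(membrane_mean = mean(.data$membrane_band_mean),
                  .groups = "drop")
      summary$membrane_by_region <- setNames(
        as.list(by_reg$membrane_mean), by_reg$region
      )
    }
  }
  if (!is.null(results$coloc)) {
    wr(results$coloc, "coloc.csv")
    summary$percent_coloc <- results$coloc$percent_coloc
  }
  if (!is.null(results$clone_tally)) {
    wr(as_tibble(results$clone_tally), "tallies.csv")
    summary$percent_inside_clone <- results$clone_tally$percent_inside
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
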