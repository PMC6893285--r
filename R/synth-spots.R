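#' Parameters for the nascent-transcription spot movie generator
#'
#' Describes two parallel rows of static nuclei (the mesectoderm geometry) in
#' which each nucleus independently and irreversibly switches its
#' transcription spot ON at `onset_delay_t0 + Exp(onset_rate_k)` minutes and
#' keeps it ON for the rest of the movie. Once ON, the spot is a 2-D Gaussian
#' of standard deviation `psf_sigma_px`; its per-spot mean amplitude is drawn
#' with coefficient of variation `cv_between_spots` across nuclei, and its
#' per-frame amplitude fluctuates (lognormally) around that mean with
#' coefficient of variation `cv_over_time`.
#'
#' Defaults reflect the biology the generator emulates: activation begins
#' roughly 30 min after the start of cellularization (`onset_delay_t0 = 30`)
#' and proceeds fast enough that nearly all nuclei are ON within about 10 min
#' of the first onsets (`onset_rate_k = 0.3` per minute gives 95% ON after
#' 10 min); spot intensity varies ~75% between nuclei at a given time but
#' only ~20% over time for a given nucleus; pixel size 0.13 um and a 3-px
#' point-spread sigma correspond to a diffraction-limited spot at that
#' sampling.
#'
#' @param n_nuclei_per_row,n_rows Nucleus grid (two rows by default).
#' @param row_spacing_um,nucleus_spacing_um Centre-to-centre spacing, um.
#' @param onset_rate_k Per-nucleus activation rate, per minute (>= 0; 0 means
#'   no nucleus ever switches ON).
#' @param onset_delay_t0 Delay before the onset process starts, minutes.
#' @param movie_start,movie_end,frame_interval Acquisition window and frame
#'   spacing, minutes.
#' @param psf_sigma_px Spot standard deviation, pixels.
#' @param mean_spot_amplitude Mean peak amplitude above background.
#' @param cv_between_spots,cv_over_time Amplitude coefficients of variation.
#' @param background_level Constant background intensity.
#' @param noise_model One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_scale Gaussian noise standard deviation (ignored for the
#'   other models).
#' @param pixel_size_um Lateral pixel size, um.
#' @param margin_px Blank border around the nucleus grid, pixels.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#'
#' @return A validated parameter list of class `spot_movie_params`.
#' @export
spot_movie_params <- function(n_nuclei_per_row = 30, n_rows = 2,
                              row_spacing_um = 5, nucleus_spacing_um = 5,
                              onset_rate_k = 0.3, onset_delay_t0 = 30,
                              movie_start = 25, movie_end = 50,
                              frame_interval = 0.5, psf_sigma_px = 3,
                              mean_spot_amplitude = 500,
                              cv_between_spots = 0.75, cv_over_time = 0.20,
                              background_level = 100,
                              noise_model = c("gaussian", "none", "poisson"),
                              noise_scale = 20, pixel_size_um = 0.13,
                              margin_px = 64, seed = NULL) {
  p <- list(
    n_nuclei_per_row = check_scalar(n_nuclei_per_row, "n_nuclei_per_row", min = 1),
    n_rows = check_scalar(n_rows, "n_rows", min = 1),
    row_spacing_um = check_scalar(row_spacing_um, "row_spacing_um", min = 0, allow_min = FALSE),
    nucleus_spacing_um = check_scalar(nucleus_spacing_um, "nucleus_spacing_um", min = 0, allow_min = FALSE),
    onset_rate_k = check_scalar(onset_rate_k, "onset_rate_k", min = 0),
    onset_delay_t0 = check_scalar(onset_delay_t0, "onset_delay_t0"),
    movie_start = check_scalar(movie_start, "movie_start"),
    movie_end = check_scalar(movie_end, "movie_end"),
    frame_interval = check_scalar(frame_interval, "frame_interval", min = 0, allow_min = FALSE),
    psf_sigma_px = check_scalar(psf_sigma_px, "psf_sigma_px", min = 0, allow_min = FALSE),
    mean_spot_amplitude = check_scalar(mean_spot_amplitude, "mean_spot_amplitude", min = 0),
    cv_between_spots = check_scalar(cv_between_spots, "cv_between_spots", min = 0),
    cv_over_time = check_scalar(cv_over_time, "cv_over_time", min = 0),
    background_level = check_scalar(background_level, "background_level", min = 0),
    noise_model = match.arg(noise_model),
    noise_scale = check_scalar(noise_scale, "noise_scale", min = 0),
    pixel_size_um = check_scalar(pixel_size_um, "pixel_size_um", min = 0, allow_min = FALSE),
    margin_px = check_scalar(margin_px, "margin_px", min = 1),
    seed = seed
  )
  if (p$movie_start > p$movie_end) {
    abort("`movie_start` must not exceed `movie_end`.")
  }
  structure(p, class = "spot_movie_params")
}

#' Generate a synthetic nascent-transcription spot movie
#'
#' Simulates the irreversible, stochastic activation of transcription spots
#' in two nucleus rows (see [spot_movie_params()]) and renders the
#' corresponding single-slice time-lapse movie with recorded ground truth.
#'
#' @param params A [spot_movie_params()] object.
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   only (`stack = NULL`); useful for kinetics simulation studies where only
#'   onset times matter.
#'
#' @return A list with components
#'   * `stack`: a [calibrated_stack()] (`T x 1 x Y x X`), or `NULL`,
#'   * `truth`: list with `nuclei` (tibble: `nucleus_id`, `row`, `index`,
#'     `x_px`, `y_px`, `onset_min` with `Inf` for never-ON,
#'     `mean_amplitude`), `amplitudes` (tibble: `nucleus_id`, `frame`,
#'     `t_min`, `amplitude` for ON nucleus-frames), `times` (frame times,
#'     minutes), `region_length_um` (grid length along the rows), and
#'     `params`.
#' @export
gen_spot_movie <- function(params, render = TRUE) {
  stopifnot(inherits(params, "spot_movie_params"))
  p <- params
  with_seed(p$seed, {
    sp_px <- p$nucleus_spacing_um / p$pixel_size_um
    row_px <- p$row_spacing_um / p$pixel_size_um
    n_nuc <- as.integer(p$n_nuclei_per_row) * as.integer(p$n_rows)
    nx <- as.integer(ceiling((p$n_nuclei_per_row - 1) * sp_px)) + 2L * p$margin_px
    ny <- as.integer(ceiling((p$n_rows - 1) * row_px)) + 2L * p$margin_px

    grid <- tidyr::expand_grid(
      row = seq_len(p$n_rows),
      index = seq_len(p$n_nuclei_per_row)
    )
    nuclei <- grid %>%
      mutate(
        nucleus_id = dplyr::row_number(),
        x_px = p$margin_px + (.data$index - 1) * sp_px,
        y_px = p$margin_px + (.data$row - 1) * row_px,
        onset_min = if (p$onset_rate_k > 0) {
          p$onset_delay_t0 + rexp(n_nuc, rate = p$onset_rate_k)
        } else {
          rep(Inf, n_nuc)
        },
        mean_amplitude = rlnorm_mean_cv(n_nuc, p$mean_spot_amplitude,
                                        p$cv_between_spots)
      ) %>%
      select("nucleus_id", "row", "index", "x_px", "y_px", "onset_min",
             "mean_amplitude")

    times <- seq(p$movie_start, p$movie_end, by = p$frame_interval)
    nt <- length(times)

    amp_tbl <- tidyr::expand_grid(nucleus_id = nuclei$nucleus_id,
                                  frame = seq_len(nt)) %>%
      mutate(t_min = times[.data$frame]) %>%
      left_join(select(nuclei, "nucleus_id", "onset_min", "mean_amplitude"),
                by = "nucleus_id") %>%
      filter(.data$onset_min <= .data$t_min)
    amp_tbl$amplitude <- amp_tbl$mean_amplitude *
      rlnorm_mean_cv(nrow(amp_tbl), 1, p$cv_over_time)
    amplitudes <- select(amp_tbl, "nucleus_id", "frame", "t_min", "amplitude")

    stack <- NULL
    if (render) {
      data <- array(0, dim = c(nt, 1L, ny, nx))
      xy <- nuclei[, c("nucleus_id", "x_px", "y_px")]
      for (t in seq_len(nt)) {
        img <- matrix(p$background_level, nrow = ny, ncol = nx)
        on_t <- amplitudes[amplitudes$frame == t, ]
        if (nrow(on_t)) {
          on_t <- left_join(on_t, xy, by = "nucleus_id")
          for (i in seq_len(nrow(on_t))) {
            img <- add_gaussian_spot(img, on_t$x_px[i], on_t$y_px[i],
                                     on_t$amplitude[i], p$psf_sigma_px)
          }
        }
        data[t, 1L, , ] <- apply_noise(img, p$noise_model, p$noise_scale)
      }
      stack <- calibrated_stack(
        data, pixel_size_um = p$pixel_size_um,
        frame_interval = p$frame_interval, time_unit = "min",
        channel_name = "MCP-GFP"
      )
    }

    list(
      stack = stack,
      truth = list(
        nuclei = nuclei,
        amplitudes = amplitudes,
        times = times,
        region_length_um = (p$n_nuclei_per_row - 1) * p$nucleus_spacing_um,
        params = p
      )
    )
  })
}

#' Convert a tissue-level activation rate to a per-nucleus rate
#'
#' Tissue-level activation is often reported as newly appearing spots per
#' minute per micrometre of tissue length. Early in activation (when nearly
#' all nuclei are still OFF) that rate equals the per-nucleus switching rate
#' `k` times the linear nucleus density, so `k = rate / density`. The nucleus
#' density is tissue-specific and must be supplied by the user.
#'
#' @param rate_per_um_min Spots per minute per um of tissue length.
#' @param nuclei_per_um Linear nucleus density (nuclei per um, all rows
#'   pooled).
#' @return Per-nucleus rate `k` in min^-1.
#' @export
nuclear_rate_from_tissue <- function(rate_per_um_min, nuclei_per_um) {
  check_scalar(rate_per_um_min, "rate_per_um_min", min = 0)
  check_scalar(nuclei_per_um, "nuclei_per_um", min = 0, allow_min = FALSE)
  rate_per_um_min / nuclei_per_um
}
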