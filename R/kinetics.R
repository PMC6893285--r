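#' Build a spot-density activation curve
#'
#' Counts detected spots per frame and converts to a linear density (spots
#' per micrometre of tissue length). Times are shifted by `alignment_time`
#' so that a chosen reference event (for these movies, the onset of ventral
#' furrow formation) sits at `t = 0`.
#'
#' @param spots A spot tibble from [detect_spots()] (needs a `frame`
#'   column), or any tibble with one row per spot. May be empty.
#' @param region_length_um Length of the measured tissue region, um (> 0).
#' @param times Frame acquisition times (raw, unshifted); one entry per
#'   frame, indexed by `frame`.
#' @param alignment_time Raw time of the alignment event; subtracted from
#'   `times`.
#' @param embryo_id,condition Provenance labels carried on the curve.
#' @return A tibble of class `activation_curve`: `frame`, `time`, `count`,
#'   `density`, with `embryo_id`, `condition`, `region_length_um`
#'   attributes.
#' @export
build_activation_curve <- function(spots, region_length_um, times,
                                   alignment_time = 0, embryo_id = NA,
                                   condition = NA) {
  check_scalar(region_length_um, "region_length_um", min = 0,
               allow_min = FALSE)
  if (!is.numeric(times) || !length(times)) {
    abort("`times` must give the acquisition time of every frame.")
  }
  counts <- if (nrow(spots)) {
    tabulate(spots$frame, nbins = length(times))
  } else {
    rep(0L, length(times))
  }
  curve <- tibble(
    frame = seq_along(times),
    time = times - alignment_time,
    count = counts,
    density = counts / region_length_um
  )
  attr(curve, "embryo_id") <- embryo_id
  attr(curve, "condition") <- condition
  attr(curve, "region_length_um") <- region_length_um
  class(curve) <- c("activation_curve", class(curve))
  curve
}

#' Saturating-exponential activation model
#'
#' `n_max * (1 - exp(-k * (t - t0)))` for `t >= t0` and 0 before `t0` (the
#' unclamped expression is negative there, so the onset branch is fixed at
#' zero).
#'
#' @param t Times.
#' @param n_max Plateau level (same scale as the fitted curve: a density for
#'   density curves).
#' @param k Activation rate, per minute.
#' @param t0 Onset delay, minutes.
#' @return Model values.
#' @export
activation_model <- function(t, n_max, k, t0) {
  ifelse(t >= t0, n_max * (1 - exp(-k * (t - t0))), 0)
}

#' Fit the saturating-exponential activation model
#'
#' Least-squares fit of `(k, t0)` with the plateau `n_max` held constant,
#' exactly as the published analysis fits spot-density curves. The fit is
#' deterministic: a fixed grid of starting values (log-spaced rates crossed
#' with onset times spanning the curve) seeds Nelder-Mead minimisation, and
#' the best start is polished with Levenberg-Marquardt.
#'
#' @param curve An [build_activation_curve()] tibble, or any data frame with
#'   `time` and `density` columns.
#' @param n_max Plateau constant, on the same scale as `density` (for a
#'   density curve, supply nuclei count divided by region length).
#' @return An object of class `exp_fit` with elements `k`, `t0`, `n_max`,
#'   `rss`, `n_points`, `converged`, and the fitted curve. An all-zero curve
#'   yields `converged = FALSE` with `k` and `t0` missing.
#' @export
fit_activation <- function(curve, n_max) {
  check_scalar(n_max, "n_max", min = 0, allow_min = FALSE)
  t <- curve$time
  y <- curve$density
  if (length(t) < 3L) abort("need at least 3 time points to fit.")
  if (is.unsorted(t, strictly = TRUE)) {
    abort("curve times must be strictly increasing.")
  }
  out <- list(k = NA_real_, t0 = NA_real_, n_max = n_max, rss = NA_real_,
              n_points = length(t), converged = FALSE, curve = curve)
  class(out) <- "exp_fit"
  if (sum(y > 0) < 3L) {
    return(out)
  }

  rss_fun <- function(par) {
    k <- exp(par[1L])
    sum((y - activation_model(t, n_max, k, par[2L]))^2)
  }
  # coarse deterministic grid, then Nelder-Mead from the best few starts
  k_grid <- log(exp(seq(log(0.005), log(10), length.out = 25L)))
  t0_grid <- unique(c(
    seq(min(t), max(t), length.out = 20L),
    t[which(y > 0)[1L]] - c(0, diff(range(t)) / 20)
  ))
  grid <- as.matrix(expand.grid(k = k_grid, t0 = t0_grid))
  vals <- apply(grid, 1L, rss_fun)
  starts <- grid[order(vals)[seq_len(3L)], , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], rss_fun, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # one restart from the winner tightens Nelder-Mead's final simplex
  best <- optim(best$par, rss_fun, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 2000))
  polished <- tryCatch({
    fit <- minpack.lm::nls.lm(
      par = list(logk = best$par[1L], t0 = best$par[2L]),
      fn = function(p) y - activation_model(t, n_max, exp(p$logk), p$t0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    p <- coef(fit)
    if (rss_fun(c(p[["logk"]], p[["t0"]])) <= best$value) {
      c(p[["logk"]], p[["t0"]])
    } else {
      best$par
    }
  }, error = function(e) best$par)

  out$k <- unname(exp(polished[1L]))
  out$t0 <- unname(polished[2L])
  out$rss <- rss_fun(polished)
  out$converged <- is.finite(out$rss)
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<exp_fit> k = %.4g /min, t0 = %.4g min (n_max = %.4g, rss = %.3g, n = %d)\n",
      x$k, x$t0, x$n_max, x$rss, x$n_points
    ))
  } else {
    cat("<exp_fit> not converged (curve carries no activation signal)\n")
  }
  invisible(x)
}

#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = c("k", "t0"), estimate = c(x$k, x$t0))
}

#' @export
glance.exp_fit <- function(x, ...) {
  tibble(n_max = x$n_max, rss = x$rss, n_points = x$n_points,
         converged = x$converged)
}

#' Compare activation fits across experimental conditions
#'
#' Summarises per-embryo rate and onset-delay estimates by condition and
#' compares each condition against a control with Welch two-sample t-tests
#' (the unequal-variance flavour of the published two-sample comparisons).
#'
#' @param fits A data frame with columns `condition`, `embryo_id`, `k`,
#'   `t0` (one row per fitted embryo), e.g. assembled from
#'   [fit_activation()] results.
#' @param control Condition label of the reference group.
#' @param alpha Significance level for flagging.
#' @return A tibble with per-condition `n`, mean and s.e.m. of `k` and
#'   `t0`, differences versus control, Welch p-values (`NA` when a group has
#'   a single embryo), and significance flags.
#' @export
compare_conditions <- function(fits, control = "control", alpha = 0.05) {
  stopifnot(all(c("condition", "k", "t0") %in% names(fits)))
  if (!control %in% fits$condition) {
    abort(paste0("control condition '", control, "' not present."))
  }
  ctrl <- filter(fits, .data$condition == control)
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  welch_p <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    t.test(a, b, var.equal = FALSE)$p.value
  }
  fits %>%
    group_by(.data$condition) %>%
    summarise(
      n = dplyr::n(),
      k_mean = mean(.data$k), k_sem = sem(.data$k),
      t0_mean = mean(.data$t0), t0_sem = sem(.data$t0),
      delta_k = mean(.data$k) - mean(ctrl$k),
      delta_t0 = mean(.data$t0) - mean(ctrl$t0),
      p_k = welch_p(.data$k, ctrl$k),
      p_t0 = welch_p(.data$t0, ctrl$t0),
      .groups = "drop"
    ) %>%
    mutate(
      sig_k = !is.na(.data$p_k) & .data$p_k < alpha,
      sig_t0 = !is.na(.data$p_t0) & .data$p_t0 < alpha
    )
}

#' Express a density curve relative to a control plateau
#'
#' Converts spot densities to the percentage of the control plateau density
#' (mean density over the control curve's final frames).
#'
#' @param curve An [build_activation_curve()] tibble.
#' @param control_curve The control-condition curve.
#' @param plateau_frames Number of trailing control frames averaged for the
#'   plateau.
#' @return `curve` with an added `percent_of_control` column.
#' @export
percent_of_control <- function(curve, control_curve, plateau_frames = 5L) {
  plateau <- mean(utils::tail(control_curve$density, plateau_frames))
  if (!is.finite(plateau) || plateau <= 0) {
    abort("control curve has no positive plateau.")
  }
  mutate(curve, percent_of_control = 100 * .data$density / plateau)
}

#' Spot-intensity stability over time and across spots
#'
#' Separates two coefficients of variation: `cv_over_time`, the mean over
#' spots of each spot's temporal CV (how much a single transcription site
#' fluctuates around its own mean), and `cv_within_timepoint`, the mean over
#' frames of the CV across spots within a frame (how different sites are
#' from one another at a given time). A stable "digital" regime shows a
#' small temporal CV next to a large between-spot CV.
#'
#' @param spots A data frame with columns `spot_id`, `frame`, `intensity`
#'   (one row per spot per frame).
#' @return A tibble of class `stability_report`: `cv_over_time`,
#'   `cv_within_timepoint`, `n_spots`, `n_frames`.
#' @export
spot_intensity_stability <- function(spots) {
  stopifnot(all(c("spot_id", "frame", "intensity") %in% names(spots)))
  if (length(unique(spots$frame)) < 2L) {
    abort("need at least 2 frames.")
  }
  per_frame <- spots %>%
    group_by(.data$frame) %>%
    summarise(n = dplyr::n(), cv = sd(.data$intensity) / mean(.data$intensity),
              .groups = "drop")
  if (all(per_frame$n < 2L)) {
    abort("need at least 2 spots in some frame.")
  }
  per_spot <- spots %>%
    group_by(.data$spot_id) %>%
    summarise(n = dplyr::n(), cv = sd(.data$intensity) / mean(.data$intensity),
              .groups = "drop") %>%
    filter(.data$n >= 2L)
  out <- tibble(
    cv_over_time = mean(per_spot$cv),
    cv_within_timepoint = mean(per_frame$cv[per_frame$n >= 2L]),
    n_spots = length(unique(spots$spot_id)),
    n_frames = length(unique(spots$frame))
  )
  class(out) <- c("stability_report", class(out))
  out
}
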