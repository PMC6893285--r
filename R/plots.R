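#' Plot an activation curve
#'
#' @param object An `activation_curve` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.activation_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$density)) +
    geom_point(size = 1) +
    geom_line(alpha = 0.4) +
    labs(x = "time (min)", y = expression("spot density (" * mu * m^-1 * ")"),
         title = attr(object, "condition")) +
    theme_minimal()
}

#' Plot an activation fit over its curve
#'
#' @param object An `exp_fit` from [fit_activation()].
#' @param ... Ignored.
#' @return A ggplot with the fitted saturating exponential overlaid.
#' @export
autoplot.exp_fit <- function(object, ...) {
  p <- autoplot(object$curve)
  if (object$converged) {
    grid <- tibble(
      time = seq(min(object$curve$time), max(object$curve$time),
                 length.out = 200)
    )
    grid$density <- activation_model(grid$time, object$n_max, object$k,
                                     object$t0)
    p <- p +
      geom_line(data = grid, colour = "firebrick") +
      labs(subtitle = sprintf("k = %.3g /min, t0 = %.3g min",
                              object$k, object$t0))
  }
  p
}

#' Plot a clustering-index time series
#'
#' Shows the raw clustering index over time plus the series scaled to its
#' final plateau (mean of the last five frames), the form in which
#' clustering kinetics are usually displayed.
#'
#' @param object A `cluster_series` tibble.
#' @param relative Add the plateau-normalised series?
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cluster_series <- function(object, relative = FALSE, ...) {
  p <- ggplot(object, aes(x = .data$t, y = .data$clustering_index)) +
    geom_line(colour = "firebrick") +
    labs(x = "time (s)", y = "clustering index") +
    theme_minimal()
  if (relative) {
    plateau <- mean(utils::tail(object$clustering_index, 5L), na.rm = TRUE)
    if (is.finite(plateau) && plateau > 0) {
      p <- p + geom_line(aes(y = .data$clustering_index / plateau),
                         linetype = 2, alpha = 0.6)
    }
  }
  p
}

#' Plot a half-time fit over its series
#'
#' @param object A `half_time_fit` from [estimate_half_time()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.half_time_fit <- function(object, ...) {
  p <- autoplot(object$series)
  if (object$converged) {
    grid <- tibble(t = seq(min(object$series$t), max(object$series$t),
                           length.out = 200))
    grid$clustering_index <- object$plateau * (1 - 2^(-grid$t / object$t_half))
    p <- p +
      geom_line(data = grid, colour = "grey30", linetype = 2) +
      labs(subtitle = sprintf("t_half = %.3g s", object$t_half))
  }
  p
}

#' Bar plot of clone-border percentages by condition
#'
#' @param summary A `proportion_summary` from [summarize_tallies()].
#' @return A ggplot with per-pupa mean +/- s.d. bars and the 50% null line.
#' @export
plot_tallies <- function(summary) {
  stopifnot(inherits(summary, "proportion_summary"))
  df <- summary$summary
  ggplot(df, aes(x = .data$condition, y = .data$mean_percent)) +
    geom_col(fill = "steelblue", width = 0.6) +
    geom_errorbar(
      aes(ymin = .data$mean_percent - .data$sd_percent,
          ymax = .data$mean_percent + .data$sd_percent),
      width = 0.15, na.rm = TRUE
    ) +
    geom_hline(yintercept = 50, linetype = 2) +
    labs(x = NULL, y = "% border SOPs inside clone") +
    theme_minimal()
}
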