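#' Score SOP fate decisions at a clone border
#'
#' Selects sensory organ precursors (SOPs) lying within `border_band_px`
#' pixels of the clone boundary and classifies each by the side of the
#' boundary it occupies (the clone-mask value at its position). The border
#' band replaces by-eye border scoring with an explicit distance criterion;
#' one proneural-cluster radius is its natural value.
#'
#' @param clone_mask Logical matrix, `TRUE` inside the clone. Must contain
#'   both inside and outside pixels.
#' @param sops A data frame of SOP positions with columns `x_px`, `y_px`
#'   (0-based pixel-centre coordinates).
#' @param border_band_px Maximum distance to the boundary, pixels.
#' @param pupa_id,condition Labels carried into the tally.
#' @return A one-row tibble of class `clone_border_tally`: `pupa_id`,
#'   `condition`, `n_sop_border`, `n_inside`, `percent_inside` (`NA` when no
#'   SOP lies at the border).
#' @export
score_border_sops <- function(clone_mask, sops, border_band_px = 8,
                              pupa_id = 1L, condition = NA_character_) {
  if (!is.matrix(clone_mask) || !is.logical(clone_mask)) {
    abort("`clone_mask` must be a logical matrix.")
  }
  if (!any(clone_mask) || all(clone_mask)) {
    abort("`clone_mask` must contain both inside and outside pixels.")
  }
  stopifnot(all(c("x_px", "y_px") %in% names(sops)))
  ny <- nrow(clone_mask)
  nx <- ncol(clone_mask)

  # boundary pixels: mask pixels 4-adjacent to a non-mask pixel, and vice versa
  shift_ne <- function(m) {
    up <- rbind(m[-1, , drop = FALSE], m[ny, , drop = FALSE])
    dn <- rbind(m[1, , drop = FALSE], m[-ny, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], m[, nx, drop = FALSE])
    rt <- cbind(m[, 1, drop = FALSE], m[, -nx, drop = FALSE])
    (m != up) | (m != dn) | (m != lf) | (m != rt)
  }
  bidx <- which(shift_ne(clone_mask))
  by <- (bidx - 1L) %% ny
  bx <- (bidx - 1L) %/% ny

  n_border <- 0L
  n_inside <- 0L
  if (nrow(sops)) {
    d <- vapply(seq_len(nrow(sops)), function(i) {
      sqrt(min((sops$x_px[i] - bx)^2 + (sops$y_px[i] - by)^2))
    }, numeric(1))
    at_border <- d <= border_band_px
    iy <- pmin(pmax(round(sops$y_px) + 1L, 1L), ny)
    ix <- pmin(pmax(round(sops$x_px) + 1L, 1L), nx)
    inside <- clone_mask[cbind(iy, ix)]
    n_border <- sum(at_border)
    n_inside <- sum(at_border & inside)
  }
  out <- tibble(
    pupa_id = pupa_id, condition = condition,
    n_sop_border = n_border, n_inside = n_inside,
    percent_inside = if (n_border > 0) 100 * n_inside / n_border else NA_real_
  )
  class(out) <- c("clone_border_tally", class(out))
  out
}

#' Summarise clone-border tallies by condition
#'
#' Per condition: the per-pupa mean and standard deviation of the percentage
#' of border SOPs inside the clone (pupae with no border SOPs are excluded),
#' an exact binomial test of the pooled counts against the unbiased 50%
#' null, and — when exactly two conditions are present — a two-sample t-test
#' on the per-pupa percentages.
#'
#' @param tallies Row-bound [score_border_sops()] tallies (columns
#'   `condition`, `pupa_id`, `n_sop_border`, `n_inside`, `percent_inside`).
#' @return An object of class `proportion_summary`: a list with `summary`
#'   (per-condition tibble with `n_pupae`, `mean_percent`, `sd_percent`,
#'   `pooled_inside`, `pooled_total`, `binom_p`) and `pairwise` (tibble of
#'   condition pairs with `t_p`, `NA` when a group has fewer than two
#'   pupae).
#' @export
summarize_tallies <- function(tallies) {
  stopifnot(all(c("condition", "n_sop_border", "n_inside") %in% names(tallies)))
  valid <- filter(tallies, .data$n_sop_border > 0)
  if (!nrow(valid)) abort("no tally has border SOPs.")
  summ <- valid %>%
    group_by(.data$condition) %>%
    summarise(
      n_pupae = dplyr::n(),
      mean_percent = mean(.data$percent_inside),
      sd_percent = if (dplyr::n() > 1L) sd(.data$percent_inside) else NA_real_,
      pooled_inside = sum(.data$n_inside),
      pooled_total = sum(.data$n_sop_border),
      .groups = "drop"
    ) %>%
    mutate(binom_p = purrr::map2_dbl(
      .data$pooled_inside, .data$pooled_total,
      ~ binom.test(.x, .y, p = 0.5)$p.value
    ))
  conds <- summ$condition
  pairwise <- tibble(condition_a = character(), condition_b = character(),
                     t_p = numeric())
  if (length(conds) >= 2L) {
    cmb <- utils::combn(conds, 2L)
    pairwise <- purrr::map(seq_len(ncol(cmb)), function(j) {
      a <- valid$percent_inside[valid$condition == cmb[1L, j]]
      b <- valid$percent_inside[valid$condition == cmb[2L, j]]
      tibble(
        condition_a = as.character(cmb[1L, j]),
        condition_b = as.character(cmb[2L, j]),
        t_p = if (length(a) > 1L && length(b) > 1L) {
          t.test(a, b)$p.value
        } else {
          NA_real_
        }
      )
    }) %>% bind_rows()
  }
  structure(list(summary = summ, pairwise = pairwise),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  cat("<proportion_summary>\n")
  print(x$summary)
  if (nrow(x$pairwise)) {
    cat("pairwise t-tests on per-pupa percentages:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' @export
tidy.proportion_summary <- function(x, ...) x$summary

#' Exact binomial test of a genotype ratio
#'
#' Tests whether two hatched-genotype counts are consistent with the
#' expected 50:50 Mendelian ratio.
#'
#' @param count_a,count_b Nonnegative counts; their sum must be positive.
#' @return A one-row tibble: `count_a`, `count_b`, `n`, `percent_a`
#'   (= 100 * a / (a + b)), `p_value` (exact two-sided binomial test against
#'   0.5).
#' @export
genotype_ratio_test <- function(count_a, count_b) {
  check_scalar(count_a, "count_a", min = 0)
  check_scalar(count_b, "count_b", min = 0)
  n <- count_a + count_b
  if (n <= 0) abort("at least one count must be positive.")
  tibble(
    count_a = count_a, count_b = count_b, n = n,
    percent_a = 100 * count_a / n,
    p_value = binom.test(round(count_a), round(n), p = 0.5)$p.value
  )
}
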