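test_that("SOPs far from the border are not scored", {
  tissue <- gen_clone_tissue(n_border_clusters = 0, n_interior_clusters = 20,
                             seed = 91)
  tally <- score_border_sops(tissue$clone_mask, tissue$sops,
                             border_band_px = 8)
  expect_equal(tally$n_sop_border, 0L)
  expect_true(is.na(tally$percent_inside))
})

test_that("unbiased tissues score near 50% and classification matches ground truth", {
  tissue <- gen_clone_tissue(n_border_clusters = 500, bias_beta = 0,
                             seed = 92)
  tally <- score_border_sops(tissue$clone_mask, tissue$sops,
                             border_band_px = 8)
  expect_equal(tally$n_sop_border, 500L)
  expect_equal(tally$n_inside, sum(tissue$sops$inside))
  se <- 100 * sqrt(0.25 / 500)
  expect_lt(abs(tally$percent_inside - 50), 3 * se)
})

test_that("relabelling inside/outside maps the percentage to its complement", {
  tissue <- gen_clone_tissue(n_border_clusters = 200, bias_beta = 1,
                             seed = 93)
  a <- score_border_sops(tissue$clone_mask, tissue$sops, 8)
  b <- score_border_sops(!tissue$clone_mask, tissue$sops, 8)
  expect_equal(a$n_sop_border, b$n_sop_border)
  expect_equal(b$percent_inside, 100 - a$percent_inside)
})

test_that("a strong bias recovers the expected inside percentage", {
  beta <- log(94.6 / 5.4)
  tissue <- gen_clone_tissue(n_border_clusters = 2000, bias_beta = beta,
                             seed = 94)
  tally <- score_border_sops(tissue$clone_mask, tissue$sops, 8)
  ci <- binom.test(tally$n_inside, tally$n_sop_border)$conf.int
  expect_true(0.946 >= ci[1] && 0.946 <= ci[2])
})

test_that("tally summaries compute per-pupa spread and exact binomial tests", {
  tallies <- dplyr::bind_rows(lapply(1:3, function(i) {
    score_border_sops(gen_clone_tissue(n_border_clusters = 40,
                                       bias_beta = 2, seed = 200 + i)$clone_mask,
                      gen_clone_tissue(n_border_clusters = 40, bias_beta = 2,
                                       seed = 200 + i)$sops,
                      8, pupa_id = i, condition = "photo")
  }))
  s <- summarize_tallies(tallies)
  expect_equal(s$summary$n_pupae, 3L)
  expect_equal(s$summary$pooled_total, 120L)
  expect_equal(s$summary$mean_percent, mean(tallies$percent_inside))

  # identical tallies: zero spread
  same <- dplyr::bind_rows(tallies[1, ], tallies[1, ])
  same$pupa_id <- 1:2
  expect_equal(summarize_tallies(same)$summary$sd_percent, 0)

  # 50/100 inside: symmetric, p = 1
  half <- tibble::tibble(pupa_id = 1L, condition = "x", n_sop_border = 100L,
                         n_inside = 50L, percent_inside = 50)
  expect_equal(summarize_tallies(half)$summary$binom_p, 1)

  # 60 of 96: cross-check against direct pmf summation
  obs <- tibble::tibble(pupa_id = 1L, condition = "x", n_sop_border = 96L,
                        n_inside = 60L, percent_inside = 100 * 60 / 96)
  got <- summarize_tallies(obs)$summary$binom_p
  pmf <- dbinom(0:96, 96, 0.5)
  want <- sum(pmf[pmf <= dbinom(60, 96, 0.5) * (1 + 1e-7)])
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("two-condition summaries include a t-test on per-pupa percentages", {
  mk <- function(beta, cond, seeds) {
    dplyr::bind_rows(lapply(seeds, function(s) {
      tis <- gen_clone_tissue(n_border_clusters = 60, bias_beta = beta,
                              seed = s)
      score_border_sops(tis$clone_mask, tis$sops, 8, pupa_id = s,
                        condition = cond)
    }))
  }
  tl <- dplyr::bind_rows(mk(0.5, "dark", 301:304), mk(2.9, "photo", 401:404))
  s <- summarize_tallies(tl)
  expect_equal(nrow(s$pairwise), 1L)
  expect_lt(s$pairwise$t_p, 0.05)
})

test_that("the genotype ratio worked example and its edge cases hold", {
  g <- genotype_ratio_test(172, 169)
  expect_equal(round(g$percent_a), 50)
  expect_gt(g$p_value, 0.05)
  expect_error(genotype_ratio_test(0, 0), "positive")
  ext <- genotype_ratio_test(100, 0)
  expect_equal(ext$percent_a, 100)
  expect_lt(ext$p_value, 1e-20)
  expect_equal(ext$p_value, 2 * 0.5^100, tolerance = 1e-9)
})

test_that("the null binomial test holds its size and the bias is recoverable", {
  # type-I over simulated unbiased tissues (moderate replicate count here;
  # the full calibration runs in the acceptance suite)
  rej <- 0L
  reps <- 300
  for (i in seq_len(reps)) {
    tis <- gen_clone_tissue(n_border_clusters = 100, bias_beta = 0,
                            seed = 5000 + i)
    tally <- score_border_sops(tis$clone_mask, tis$sops, 8)
    if (binom.test(tally$n_inside, tally$n_sop_border)$p.value < 0.05) {
      rej <- rej + 1L
    }
  }
  expect_gte(rej / reps, 0.02)
  expect_lte(rej / reps, 0.09)

  for (beta in c(0, 1, 2, 3)) {
    tis <- gen_clone_tissue(n_border_clusters = 5000, bias_beta = beta,
                            seed = 6000 + beta)
    tally <- score_border_sops(tis$clone_mask, tis$sops, 8)
    beta_hat <- stats::qlogis(tally$n_inside / tally$n_sop_border)
    expect_lt(abs(beta_hat - beta), 0.2)
  }
})
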