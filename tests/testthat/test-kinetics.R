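# build a spot tibble and times from generator ground truth (perfect
# detection): one row per ON nucleus per frame
truth_spots <- function(truth) {
  tibble::tibble(frame = truth$amplitudes$frame)
}

test_that("activation curves are counts over length with shifted times", {
  spots <- tibble::tibble(frame = rep(3L, 10))
  cv <- build_activation_curve(spots, region_length_um = 50,
                               times = c(0, 1, 2, 3))
  expect_equal(cv$density, c(0, 0, 0.2, 0))
  shifted <- build_activation_curve(spots, 50, times = c(0, 1, 2, 3),
                                    alignment_time = 2)
  expect_equal(shifted$density, cv$density)
  expect_equal(shifted$time, cv$time - 2)
  empty <- build_activation_curve(spots[0, ], 50, times = 0:3)
  expect_equal(empty$density, rep(0, 4))
})

test_that("ground-truth curves equal the cumulative count of onsets", {
  m <- gen_spot_movie(spot_movie_params(
    n_nuclei_per_row = 30, onset_rate_k = 0.3, onset_delay_t0 = 30,
    movie_start = 25, movie_end = 50, frame_interval = 0.5, seed = 8
  ), render = FALSE)
  cv <- build_activation_curve(truth_spots(m$truth),
                               m$truth$region_length_um, m$truth$times)
  cum <- vapply(m$truth$times,
                function(tm) sum(m$truth$nuclei$onset_min <= tm), numeric(1))
  expect_equal(cv$count, as.integer(cum))
  expect_equal(cv$density, cum / m$truth$region_length_um)
  expect_true(all(diff(cv$count) >= 0))
})

test_that("noiseless model curves are recovered to 1e-6 relative accuracy", {
  set.seed(51)
  for (i in 1:20) {
    k <- exp(runif(1, log(0.05), log(1)))
    t0 <- runif(1, 5, 35)
    tm <- seq(0, 60, by = 0.5)
    cv <- tibble::tibble(time = tm,
                         density = activation_model(tm, 0.4, k, t0))
    f <- fit_activation(cv, 0.4)
    expect_true(f$converged)
    expect_lt(abs(f$k - k) / k, 1e-6)
    expect_lt(abs(f$t0 - t0) / t0, 1e-6)
  }
})

test_that("the fit ignores leading all-zero time points", {
  tm <- seq(10, 60, by = 0.5)
  cv <- tibble::tibble(time = tm, density = activation_model(tm, 0.4, 0.3, 30))
  f0 <- fit_activation(cv, 0.4)
  pre <- tibble::tibble(time = seq(0, 9.5, by = 0.5), density = 0)
  f1 <- fit_activation(dplyr::bind_rows(pre, cv), 0.4)
  expect_equal(f1$k, f0$k, tolerance = 1e-6)
  expect_equal(f1$t0, f0$t0, tolerance = 1e-6)
})

test_that("an all-zero curve is flagged, with the rate reported as missing", {
  cv <- tibble::tibble(time = 0:10, density = 0)
  f <- fit_activation(cv, 0.4)
  expect_false(f$converged)
  expect_true(is.na(f$k))
  expect_true(is.na(f$t0))
})

sim_khat <- function(k, seed, n_per_row = 30, t0 = 30) {
  m <- gen_spot_movie(spot_movie_params(
    n_nuclei_per_row = n_per_row, onset_rate_k = k, onset_delay_t0 = t0,
    movie_start = 25, movie_end = 55, frame_interval = 0.5, seed = seed
  ), render = FALSE)
  cv <- build_activation_curve(truth_spots(m$truth),
                               m$truth$region_length_um, m$truth$times)
  f <- fit_activation(cv, nrow(m$truth$nuclei) / m$truth$region_length_um)
  c(khat = f$k, t0hat = f$t0)
}

test_that("stochastic embryos recover the rate near the maximum-likelihood oracle", {
  ests <- vapply(1:8, function(s) sim_khat(0.3, seed = 600 + s),
                 c(khat = 0, t0hat = 0))
  # ML oracle on the ground-truth onset times of the same embryos
  for (s in 1:4) {
    m <- gen_spot_movie(spot_movie_params(
      n_nuclei_per_row = 30, onset_rate_k = 0.3, onset_delay_t0 = 30,
      movie_start = 25, movie_end = 55, frame_interval = 0.5, seed = 600 + s
    ), render = FALSE)
    waits <- m$truth$nuclei$onset_min - 30
    mle <- 1 / mean(waits[is.finite(waits)])
    expect_lt(abs(ests["khat", s] - mle) / mle, 0.35)
  }
  expect_lt(median(abs(ests["khat", ] - 0.3)) / 0.3, 0.25)
  expect_lt(median(abs(ests["t0hat", ] - 30)), 0.5)
})

test_that("doubling the true rate increases the median estimated rate", {
  med <- vapply(c(0.1, 0.2, 0.4), function(k) {
    median(vapply(1:6, function(s) sim_khat(k, seed = 900 + s)[1], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("condition comparisons behave on identical and separated groups", {
  fits <- tibble::tibble(
    condition = rep(c("control", "treated"), each = 4),
    embryo_id = 1:8,
    k = rep(c(0.31, 0.29, 0.30, 0.32), 2),
    t0 = rep(c(30, 31, 29, 30), 2)
  )
  cmp <- compare_conditions(fits, control = "control")
  tr <- cmp[cmp$condition == "treated", ]
  expect_equal(tr$delta_k, 0)
  expect_gt(tr$p_k, 0.99)
  expect_false(tr$sig_k)

  # separated: k around 0.2 vs 0.05
  set.seed(52)
  fits2 <- tibble::tibble(
    condition = rep(c("control", "short"), each = 6),
    embryo_id = 1:12,
    k = c(rnorm(6, 0.2, 0.02), rnorm(6, 0.05, 0.01)),
    t0 = c(rnorm(6, 30, 1), rnorm(6, 40, 1))
  )
  cmp2 <- compare_conditions(fits2, control = "control")
  sh <- cmp2[cmp2$condition == "short", ]
  expect_lt(sh$p_k, 0.05)
  expect_lt(sh$delta_k, 0)
  expect_gt(sh$delta_t0, 0)

  # single-embryo condition: reported, but without a p-value
  fits3 <- dplyr::bind_rows(fits, tibble::tibble(
    condition = "solo", embryo_id = 9L, k = 0.1, t0 = 35
  ))
  cmp3 <- compare_conditions(fits3, control = "control")
  expect_true(is.na(cmp3$p_k[cmp3$condition == "solo"]))
})

test_that("the Welch comparison rejects strong rate differences and holds its size", {
  reps <- 60
  hits <- 0L
  for (r in 1:reps) {
    a <- vapply(1:4, function(s) sim_khat(0.2, seed = 2000 + 10 * r + s,
                                          n_per_row = 15)[1], numeric(1))
    b <- vapply(1:4, function(s) sim_khat(0.05, seed = 5000 + 10 * r + s,
                                          n_per_row = 15)[1], numeric(1))
    fits <- tibble::tibble(
      condition = rep(c("control", "short"), each = 4),
      embryo_id = 1:8, k = c(a, b), t0 = 0
    )
    cmp <- compare_conditions(fits, control = "control")
    if (cmp$p_k[cmp$condition == "short"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("percent-of-control scales by the control plateau", {
  tm <- 0:20
  ctrl <- build_activation_curve(
    tibble::tibble(frame = rep(17:21, each = 40)), 100, times = tm
  )
  cv <- build_activation_curve(tibble::tibble(frame = rep(21L, 20)), 100,
                               times = tm)
  out <- percent_of_control(cv, ctrl)
  expect_equal(out$percent_of_control[21], 50)
})

test_that("stability separates temporal from between-spot variation", {
  # constant intensities: both CVs zero
  const <- dplyr::mutate(tidyr::expand_grid(spot_id = 1:5, frame = 1:10),
                         intensity = 100)
  rep0 <- spot_intensity_stability(const)
  expect_equal(rep0$cv_over_time, 0)
  expect_equal(rep0$cv_within_timepoint, 0)

  # generator regime: between-spot CV 0.75, temporal CV 0.20
  m <- gen_spot_movie(spot_movie_params(
    n_nuclei_per_row = 30, onset_rate_k = 50, onset_delay_t0 = -1,
    movie_start = 0, movie_end = 19.5, frame_interval = 0.5,
    cv_between_spots = 0.75, cv_over_time = 0.20, seed = 61
  ), render = FALSE)
  spots <- dplyr::transmute(m$truth$amplitudes,
                            spot_id = nucleus_id,
                            frame = frame,
                            intensity = amplitude)
  rep1 <- spot_intensity_stability(spots)
  expect_gt(rep1$n_spots, 50)
  expect_equal(rep1$cv_over_time, 0.20, tolerance = 0.20)
  expect_equal(rep1$cv_within_timepoint, 0.75, tolerance = 0.20)
  expect_gt(rep1$cv_within_timepoint, rep1$cv_over_time)

  # relabelling frames (a bijection) leaves the within-frame CV unchanged
  perm <- sample(unique(spots$frame))
  relabelled <- dplyr::mutate(spots, frame = perm[match(frame, sort(unique(frame)))])
  rep2 <- spot_intensity_stability(relabelled)
  expect_equal(rep2$cv_within_timepoint, rep1$cv_within_timepoint)

  expect_error(spot_intensity_stability(const[const$frame == 1, ]), "frames")
})
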