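small_movie_params <- function(...) {
  defaults <- list(
    n_nuclei_per_row = 4, margin_px = 52, movie_start = 0, movie_end = 10,
    frame_interval = 2, onset_delay_t0 = 2, onset_rate_k = 0.5
  )
  do.call(spot_movie_params, utils::modifyList(defaults, list(...)))
}

test_that("identical parameters and seed give bit-identical movies and ground truth", {
  a <- gen_spot_movie(small_movie_params(seed = 42))
  b <- gen_spot_movie(small_movie_params(seed = 42))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  c <- gen_spot_movie(small_movie_params(seed = 43))
  expect_false(identical(a$stack$data, c$stack$data))

  v1 <- gen_vesicle_field(n_vesicles = 20, frame_px = 256, seed = 5)
  v2 <- gen_vesicle_field(n_vesicles = 20, frame_px = 256, seed = 5)
  expect_identical(v1$stack_a$data, v2$stack_a$data)
  expect_identical(v1$truth$vesicles, v2$truth$vesicles)

  t1 <- gen_clone_tissue(n_border_clusters = 30, seed = 9)
  t2 <- gen_clone_tissue(n_border_clusters = 30, seed = 9)
  expect_identical(t1$sops, t2$sops)
})

test_that("generators run without touching the caller's RNG stream", {
  set.seed(100)
  before <- .Random.seed
  gen_spot_movie(small_movie_params(seed = 1), render = FALSE)
  gen_clone_tissue(n_border_clusters = 5, seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("zero onset rate means no nucleus ever switches on", {
  m <- gen_spot_movie(small_movie_params(onset_rate_k = 0, noise_model = "none",
                                         seed = 1))
  expect_true(all(is.infinite(m$truth$nuclei$onset_min)))
  expect_equal(max(m$stack$data), m$truth$params$background_level)
  expect_equal(nrow(m$truth$amplitudes), 0L)
})

test_that("recorded onset times minus t0 follow the exponential law", {
  m <- gen_spot_movie(spot_movie_params(
    n_nuclei_per_row = 300, n_rows = 2, onset_rate_k = 0.3,
    onset_delay_t0 = 5, seed = 77
  ), render = FALSE)
  waits <- m$truth$nuclei$onset_min - 5
  expect_true(all(waits >= 0))
  expect_gt(ks.test(waits, "pexp", 0.3)$p.value, 0.01)
})

test_that("negative or non-finite generator parameters are rejected", {
  expect_error(spot_movie_params(onset_rate_k = -1), "onset_rate_k")
  expect_error(spot_movie_params(pixel_size_um = 0), "pixel_size_um")
  expect_error(spot_movie_params(movie_start = 10, movie_end = 0),
               "movie_start")
  expect_error(cluster_movie_params(f_max = 0), "f_max")
  expect_error(cluster_movie_params(f_max = 1.2), "f_max")
  expect_error(cluster_movie_params(half_time_s = -3), "half_time_s")
})

test_that("cluster movies start uniform, hit f_max/2 at the half-time, and conserve intensity", {
  p <- cluster_movie_params(duration_s = 120, frame_interval_s = 40,
                            half_time_s = 40, f_max = 0.8, seed = 3)
  m <- gen_cluster_movie(p)
  f <- m$truth$f_series
  expect_equal(f$f[f$t_s == 0], 0)
  expect_equal(f$f[f$t_s == 40], 0.8 / 2)
  sums <- vapply(seq_len(nrow(f)),
                 function(t) sum(stack_frame(m$stack, t)), numeric(1))
  expect_equal(sums, rep(p$total_intensity, nrow(f)), tolerance = 1e-12)
  # first frame: all membrane pixels share one uniform value
  fr1 <- stack_frame(m$stack, 1)
  expect_equal(length(unique(fr1[m$truth$membrane_mask])), 1L)
})

test_that("interface images honour the depletion factor and ridge construction", {
  g1 <- gen_interface_image(depletion_factor = 1)
  expect_equal(unname(g1$truth$ridge_amplitude["mesoderm"] /
                        g1$truth$ridge_amplitude["ectoderm"]), 1)
  g <- gen_interface_image(depletion_factor = 0.3)
  expect_equal(unname(g$truth$ridge_amplitude["mesoderm"] /
                        g$truth$ridge_amplitude["ectoderm"]), 0.3)
  # no cytoplasm, no noise: intensity confined to the ridge band
  g0 <- gen_interface_image(cytoplasm_level = 0, noise_model = "none")
  img <- stack_frame(g0$stack)
  far <- g0$truth$dist_px > 5 * g0$truth$ridge_sigma_px
  expect_lt(sum(img[far]), 1e-4 * sum(img))
  # labels tile the image and regions split at the boundary
  expect_true(all(g$labels$cells > 0))
  expect_setequal(unique(as.integer(g$labels$region)), c(1L, 2L))
})

test_that("vesicle fields realize the requested overlap structure", {
  all_in <- gen_vesicle_field(n_vesicles = 30, overlap_fraction = 1,
                              frame_px = 256, seed = 21)
  expect_true(all(all_in$truth$vesicles$overlaps))
  none <- gen_vesicle_field(n_vesicles = 30, overlap_fraction = 0,
                            frame_px = 256, seed = 22)
  expect_false(any(none$truth$vesicles$overlaps))
  expect_false(any(none$truth$mask_a & none$truth$mask_b))
  mid <- gen_vesicle_field(n_vesicles = 100, overlap_fraction = 0.75,
                           frame_px = 420, seed = 23)
  expect_equal(sum(mid$truth$vesicles$overlaps),
               sum(mid$truth$vesicles$partner))
  expect_error(gen_vesicle_field(n_vesicles = 5000, frame_px = 128),
               "too many")
})

test_that("clone tissue respects the null and the saturated bias", {
  null <- gen_clone_tissue(n_border_clusters = 10000, bias_beta = 0,
                           seed = 31)
  frac <- mean(null$sops$inside)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
  sat <- gen_clone_tissue(n_border_clusters = 500, bias_beta = Inf, seed = 32)
  expect_true(all(sat$sops$inside))
  # ground-truth side always agrees with the mask at the SOP position
  iy <- round(null$sops$y_px) + 1L
  ix <- round(null$sops$x_px) + 1L
  expect_identical(null$clone_mask[cbind(iy, ix)], null$sops$inside)
})

test_that("tissue-level rates convert to per-nucleus rates through density", {
  expect_equal(nuclear_rate_from_tissue(0.2, 0.4), 0.5)
  expect_error(nuclear_rate_from_tissue(0.2, 0), "nuclei_per_um")
})
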