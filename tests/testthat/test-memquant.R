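erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1

ridge_image <- function(ny, nx, xc_px, amp, sigma_um, pixel_size_um) {
  x <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
  amp * exp(-((x - xc_px) * pixel_size_um)^2 / (2 * sigma_um^2))
}

test_that("sum projections are identities, sums, and additive over slice ranges", {
  arr <- array(runif(3 * 4 * 10 * 10), dim = c(3, 4, 10, 10))
  st <- calibrated_stack(arr, pixel_size_um = 0.1)
  expect_equal(project_sum(st, 1, t = 2, z_start = 3),
               stack_frame(st, 2, 3))
  ones <- calibrated_stack(array(1, dim = c(1, 10, 8, 8)),
                           pixel_size_um = 0.1)
  expect_equal(project_sum(ones, 10), matrix(10, 8, 8))
  expect_equal(project_sum(st, 2, t = 1, z_start = 1) +
                 project_sum(st, 2, t = 1, z_start = 3),
               project_sum(st, 4, t = 1))
  expect_error(project_sum(st, 5), "slice range")
})

test_that("the interface integral matches the closed-form Gaussian-ridge expression", {
  a <- 150
  sig <- 0.15
  w <- 0.78
  expected <- a * sig * sqrt(2 * pi) * erf((w / 2) / (sqrt(2) * sig))
  errs <- vapply(c(0.15, 0.1, 0.05), function(px) {
    img <- ridge_image(41, 161, 80, a, sig, px)
    m <- measure_interface(img, x0 = 80 - 30, y0 = 20, x1 = 80 + 30, y1 = 20,
                           pixel_size_um = px)
    expect_false(m$flagged)
    abs(m$integrated_intensity - expected) / expected
  }, numeric(1))
  expect_lt(errs[3], 0.005)
  expect_true(all(diff(errs) < 0))

  # linearity in amplitude
  img1 <- ridge_image(41, 161, 80, a, sig, 0.05)
  img2 <- ridge_image(41, 161, 80, 2 * a, sig, 0.05)
  m1 <- measure_interface(img1, 50, 20, 110, 20, 0.05)
  m2 <- measure_interface(img2, 50, 20, 110, 20, 0.05)
  expect_equal(m2$integrated_intensity, 2 * m1$integrated_intensity,
               tolerance = 1e-9)
})

test_that("flat profiles are flagged with zero integral and clipping is reported", {
  flat <- matrix(0, 30, 60)
  m <- measure_interface(flat, 5, 15, 55, 15, pixel_size_um = 0.1)
  expect_true(m$flagged)
  expect_equal(m$integrated_intensity, 0)
  # a peak right at the end of a short profile forces clipping
  img <- ridge_image(31, 61, 55, 100, 0.15, 0.05)
  mc <- measure_interface(img, 40, 15, 58, 15, pixel_size_um = 0.05)
  expect_true(mc$clipped)
})

test_that("normalisation to the reference region divides by its median", {
  ms <- tibble::tibble(
    region = c("ectoderm", "ectoderm", "ectoderm", "mesoderm"),
    integrated_intensity = c(10, 10, 10, 13)
  )
  out <- normalize_to_reference(ms)
  expect_equal(out$normalized_intensity, c(1, 1, 1, 1.3))
  expect_error(
    normalize_to_reference(ms[ms$region == "mesoderm", ]),
    "ectoderm"
  )
  # per-embryo normalisation
  ms2 <- dplyr::bind_rows(
    dplyr::mutate(ms, embryo_id = "e1"),
    dplyr::mutate(ms, embryo_id = "e2",
                  integrated_intensity = integrated_intensity * 5)
  )
  out2 <- normalize_to_reference(ms2)
  expect_equal(out2$normalized_intensity[out2$region == "mesoderm"],
               c(1.3, 1.3))
})

test_that("membrane bands have the stated thickness and exact compartment means", {
  labels <- matrix(0L, 100, 100)
  labels[20:59, 20:59] <- 1L
  ii <- matrix(seq_len(100), 100, 100)
  jj <- t(ii)
  d <- pmin(ii - 19, 60 - ii, jj - 19, 60 - jj)  # distance to nearest outside px
  img <- matrix(0, 100, 100)
  img[labels == 1L & d <= 3] <- 200
  img[labels == 1L & d > 3] <- 100
  q <- membrane_band_quant(img, labels, pixel_size_um = 0.1, band_um = 0.3)
  expect_equal(q$membrane_band_mean, 200)
  expect_equal(q$cytoplasm_mean, 100)
  expect_equal(q$cyt_to_mem_ratio, 0.5)
  expect_false(q$flagged)
  # the package band equals the analytic <= 0.3 um band exactly
  expect_equal(q$n_band_px, sum(labels == 1L & d <= 3))

  # uniform image: ratio 1
  q1 <- membrane_band_quant(matrix(4, 100, 100), labels, 0.1)
  expect_equal(q1$cyt_to_mem_ratio, 1)

  # a cell thinner than the band is flagged
  thin <- matrix(0L, 50, 50)
  thin[10:13, 10:40] <- 1L
  qt <- membrane_band_quant(matrix(1, 50, 50), thin, 0.1, band_um = 0.3)
  expect_true(qt$flagged)
})

test_that("the synthetic depleted region shows the expected membrane ratio", {
  g <- gen_interface_image(depletion_factor = 0.3)
  q <- membrane_band_quant(stack_frame(g$stack), g$labels$cells,
                           pixel_size_um = g$stack$pixel_size_um,
                           region = g$labels$region)
  means <- tapply(q$membrane_band_mean, q$region, mean)
  expect_equal(unname(means["mesoderm"] / means["ectoderm"]), 0.30,
               tolerance = 0.1)
  expect_lt(abs(means["mesoderm"] / means["ectoderm"] - 0.30), 0.03)
})

test_that("colocalization is 100% for identical channels and 0% for disjoint ones", {
  img <- oracle_spot_image(150, 150, cbind(c(50, 100), c(50, 100)), 800, 2,
                           background = 10)
  st <- calibrated_stack(img, pixel_size_um = 0.13)
  same <- coloc_percent(st, st)
  expect_equal(same$percent_coloc, 100)
  img_b <- oracle_spot_image(150, 150, cbind(c(50, 100), c(100, 50)), 800, 2,
                             background = 10)
  stb <- calibrated_stack(img_b, pixel_size_um = 0.13)
  disj <- coloc_percent(st, stb)
  expect_equal(disj$percent_coloc, 0)
})

test_that("colocalization matches generator bookkeeping exactly on noise-free fields", {
  f <- gen_vesicle_field(n_vesicles = 60, overlap_fraction = 0.6,
                         frame_px = 360, seed = 81)
  res <- coloc_percent(f$stack_a, f$stack_b)
  expect_equal(res$n_a, 60)
  expect_equal(res$percent_coloc, 100 * mean(f$truth$vesicles$overlaps))
})
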