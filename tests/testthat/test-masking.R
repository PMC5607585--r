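test_that("temperature standard deviation follows sqrt(2)/(SNR k)", {
  acq <- acquisition_params()
  # SNR 9.37 at the nominal coefficient sits exactly at the 2 degC rule
  s <- temperature_std_map(matrix(9.37 * 0.02, 2, 2), 0.02, acq, 0.0094)
  expect_equal(s[1, 1], 2, tolerance = 2e-3)
  # inverse proportionality and the high-SNR limit
  expect_equal(temperature_std_map(matrix(1), 0.02, acq),
               2 * temperature_std_map(matrix(2), 0.02, acq))
  expect_lt(temperature_std_map(matrix(1e6), 0.02, acq)[1], 1e-4)
  expect_error(temperature_std_map(matrix(1), 0, acq), "positive")
})

test_that("a constructed void is masked exactly, and masking is anti-monotone in SNR", {
  mag <- matrix(1, 16, 16)
  u <- (row(mag) - 8.5) / 3
  v <- (col(mag) - 8.5) / 2.2
  void <- u^2 + v^2 <= 1
  mag[void] <- 0
  sig <- temperature_std_map(mag, 0.02, acquisition_params())
  expect_identical(unname(mask_frame(sig, 2)), unname(void))
  expect_equal(sum(mask_frame(sig, 2)), sum(void))
  # a 1 degC threshold masks a superset of the 2 degC mask
  expect_true(all(mask_frame(sig, 2) <= mask_frame(sig, 1)))
  # raising every magnitude never adds a masked voxel
  sig_hi <- temperature_std_map(mag * 1.5 + 0.01, 0.02, acquisition_params())
  expect_true(all(mask_frame(sig_hi, 2) <= mask_frame(sig, 2)))
})

test_that("majority masking uses a strict one-half rule", {
  m <- function(on) matrix(on, 1, 1)
  expect_true(majority_mask(simplify2array(list(m(TRUE), m(TRUE), m(TRUE))))[1])
  # exactly half of an even count is excluded
  expect_false(majority_mask(simplify2array(list(m(TRUE), m(TRUE),
                                                 m(FALSE), m(FALSE))))[1])
  expect_true(majority_mask(simplify2array(list(m(TRUE), m(TRUE), m(TRUE),
                                                m(FALSE), m(FALSE))))[1])
  expect_error(majority_mask(array(TRUE, c(2, 2, 0))), "at least one")
})

test_that("infilling averages valid neighbours and preserves the rest", {
  map <- matrix(10, 5, 5)
  mask <- matrix(FALSE, 5, 5)
  mask[3, 3] <- TRUE
  expect_equal(infill_masked(map, mask)[3, 3], 10)
  # 4-neighbourhood arithmetic
  map2 <- matrix(0, 3, 3)
  map2[2, 1] <- 1; map2[1, 2] <- 2; map2[3, 2] <- 3; map2[2, 3] <- 4
  mask2 <- matrix(FALSE, 3, 3); mask2[2, 2] <- TRUE
  expect_equal(infill_masked(map2, mask2, neighborhood = 4)[2, 2], 2.5)
  # empty mask is the identity; unmasked voxels are untouched bit-exactly
  set.seed(1)
  noisy <- matrix(rnorm(100), 10, 10)
  expect_identical(infill_masked(noisy, matrix(FALSE, 10, 10)), noisy)
  mask3 <- matrix(FALSE, 10, 10); mask3[4:6, 4:6] <- TRUE
  filled <- infill_masked(noisy, mask3)
  expect_identical(filled[!mask3], noisy[!mask3])
  expect_true(all(is.finite(filled)))
  # a block with an interior voxel having no valid neighbour fills iteratively
  expect_true(is.finite(filled[5, 5]))
  expect_error(infill_masked(noisy, matrix(TRUE, 10, 10)), "fully masked")
})

test_that("mask reports compute volumes, ratios and growth", {
  g <- scan_grid()
  marker <- marker_spec("BiomarC 2x4", "carbon_coated", "cylinder", 2, 4)
  masks <- array(FALSE, c(8, 8, 4))
  masks[2, 2:6, ] <- TRUE                  # 5 voxels in every frame
  rep5 <- mask_report(masks, g, marker)
  expect_equal(rep5$majority_count, 5)
  expect_equal(rep5$masked_volume_mm3, 5 * 1.56^2 * 5, tolerance = 1e-9)
  expect_equal(rep5$ratio_to_marker_volume, 60.84 / 12.57, tolerance = 1e-3)
  # growth factor from first to last frame counts
  masks2 <- array(FALSE, c(8, 8, 2))
  masks2[1, 1:5, 1] <- TRUE
  masks2[1:3, 1:3, 2] <- TRUE
  rep2 <- mask_report(masks2, g, marker)
  expect_equal(rep2$growth_factor, 9 / 5)
  # empty masks: zero counts, absent growth
  rep0 <- mask_report(array(FALSE, c(8, 8, 3)), g, marker)
  expect_equal(rep0$majority_count, 0)
  expect_true(is.na(rep0$growth_factor))
})

test_that("noise sigma estimation recovers the injected noise level", {
  imgs <- render_images(mini_field(), NULL, signal_model(baseline_snr = 40),
                        acquisition_params(), mini_image_grid(),
                        rng_seed = 5, orientations = "coronal")
  est <- estimate_noise_sigma(imgs$coronal)
  expect_equal(est, 1 / 40, tolerance = 0.15)
})

test_that("on heated marker series the masked count grows with temperature", {
  f <- mini_field()
  m <- marker_from_catalogue("Gold Anchor 2.1x2.1")
  imgs <- render_images(f, m, signal_model(), acquisition_params(),
                        mini_image_grid(), rng_seed = 7,
                        orientations = "coronal")
  ns <- estimate_noise_sigma(imgs$coronal)
  sig <- temperature_std_map(imgs$coronal$magnitude, ns,
                             acquisition_params())
  counts <- apply(mask_frame(sig, 2), 3, sum)
  t <- imgs$coronal$times
  # pre-heating voxels are already masked (the void exists before heating)
  expect_gt(mean(counts[t < 3]), 0)
  # counts at the end of sonication exceed the pre-heating counts
  expect_gt(mean(counts[t >= 8 & t <= 9]), mean(counts[t < 3]))
})
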