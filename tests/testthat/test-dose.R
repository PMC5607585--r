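test_that("CEM43 accumulation matches its closed forms", {
  cfg <- dose_config()
  # 240 minutes at the breakpoint is 240 EM
  d1 <- cem43(array(43 - 37, c(1, 1, 240)), 60, cfg)
  expect_equal(d1[1, 1], 240, tolerance = 1e-9)
  # 14.0625 s at 53 degC: R^-10 = 1024, 1024 * 0.234375 min = 240 EM
  d2 <- cem43(array(53 - 37, c(1, 1, 1)), 14.0625, cfg)
  expect_equal(d2[1, 1], 240, tolerance = 1e-9)
  # one minute at baseline
  d3 <- cem43(array(0, c(1, 1, 1)), 60, cfg)
  expect_equal(d3[1, 1], 0.25^6, tolerance = 1e-12)
  expect_error(cem43(array(0, c(1, 1, 1)), -1, cfg), ">= 0")
})

test_that("CEM43 is monotone in temperature and additive over time", {
  set.seed(8)
  base <- array(runif(4 * 4 * 10, 0, 20), c(4, 4, 10))
  d <- cem43(base, 2)
  hotter <- base
  hotter[2, 2, 5] <- hotter[2, 2, 5] + 3
  expect_true(all(cem43(hotter, 2) >= d))
  # additivity: dose(all frames) = dose(first half) + dose(second half)
  expect_equal(d, cem43(base[, , 1:5], 2) + cem43(base[, , 6:10], 2),
               tolerance = 1e-12)
})

test_that("the two-plane reconstruction is exact on separable fields", {
  # 3D Gaussian on the package's half-integer lattice: separable, so the
  # normalised product of the two planes through the focus is exact
  ax <- (seq_len(14) - 7.5) * 1.56
  fx <- exp(-ax^2 / 30); fy <- exp(-ax^2 / 18); fz <- exp(-ax^2 / 8)
  truth <- outer(outer(fx, fy), fz) * 25
  coronal <- truth[, , 7]   # z = z0 plane
  sagittal <- truth[7, , ]  # x = x0 plane
  rec <- reconstruct_3d(coronal, sagittal, eps_fraction = 1e-12)
  expect_equal(as.vector(rec), as.vector(truth), tolerance = 1e-9)
  # the peak (and hence every -6 dB width) is recovered exactly here
  expect_equal(max(rec), max(truth), tolerance = 1e-9)
  # zero maps give a zero volume, and mismatched planes warn
  expect_true(all(reconstruct_3d(matrix(0, 14, 14), matrix(0, 14, 14)) == 0))
  expect_warning(reconstruct_3d(coronal, 2 * sagittal), "disagree")
})

test_that("dose volume counts super-threshold voxels and is monotone in threshold", {
  off <- (seq(-8, 7) + 0.5) * 1.56
  gr <- expand.grid(x = off, y = off, z = off)
  inside <- (gr$x / 6)^2 + (gr$y / 6)^2 + (gr$z / 4)^2 <= 1
  dose <- array(ifelse(inside, 1000, 1), c(16, 16, 16))
  v <- dose_volume(dose, 1.56^3, 240)
  expect_equal(v, ellipsoid_volume(c(12, 12, 8)), tolerance = 0.03)
  expect_equal(dose_volume(array(1, c(4, 4, 4)), 1.56^3, 240), 0)
  expect_equal(dose_volume(array(1, c(4, 4, 4)), 1.56^3, 0),
               64 * 1.56^3 / 1000)
  thr <- c(0, 10, 240, 2000)
  vols <- vapply(thr, function(t) dose_volume(dose, 1.56^3, t), numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("maximum unmasked temperature respects the masking rule", {
  tms <- structure(list(dT = array(0, c(4, 4, 2)), times = c(1, 2),
                        valid = array(TRUE, c(4, 4, 2)),
                        grid = scan_grid(fov_mm = 6.24, n_rows = 4,
                                         n_cols = 4),
                        k_rad_per_C = 0.075, alpha = 0.0094,
                        average_factor = 1L, sonication = NULL),
                   class = "thermal_map_series")
  tms$dT[2, 2, 2] <- 28.4
  sig <- array(0.5, c(4, 4, 2))
  expect_equal(max_unmasked_temperature(tms, sig), 28.4)
  # the hottest voxel masked: the runner-up wins
  tms$dT[3, 3, 2] <- 20
  sig[2, 2, 2] <- 5
  expect_equal(max_unmasked_temperature(tms, sig), 20)
  # the averaged rule (1 degC) applies to averaged series
  tms$average_factor <- 4L
  sig[] <- 1.5; sig[3, 3, 2] <- 0.5
  expect_equal(max_unmasked_temperature(tms, sig), 20)
  sig[] <- 5
  expect_error(max_unmasked_temperature(tms, sig), "all voxels masked")
})

test_that("edge-annulus means agree with direct enumeration", {
  g <- scan_grid()
  uniform <- matrix(17, 128, 128)
  expect_equal(edge_mean_temperature(uniform, g), 17)
  # radially linear field: the mean equals the mean radius of the 28 centres
  r <- sqrt(outer((seq_len(128) - 64.5) * 1.56, (seq_len(128) - 64.5) * 1.56,
                  function(a, b) a^2 + b^2))
  vox <- voxel_centers_in_region(g, region_spec("annulus", 12, 9))
  expect_equal(edge_mean_temperature(r, g), mean(vox$r_mm), tolerance = 1e-9)
  # infilling a constant field does not change the mean
  mask <- matrix(FALSE, 128, 128); mask[60:68, 60:68] <- TRUE
  expect_equal(edge_mean_temperature(infill_masked(uniform, mask), g), 17)
})

test_that("apparent marker size measures void extents along principal axes", {
  g <- scan_grid(fov_mm = 100, n_rows = 64, n_cols = 64)
  img <- matrix(1, 64, 64)
  expect_equal(unname(apparent_marker_size(img, g)), c(0, 0))
  img[30:33, 25:32] <- 0.1  # 4 x 8 voxel rectangle
  sz <- apparent_marker_size(img, g)
  expect_equal(unname(sz), c(4, 8) * 1.56, tolerance = 1e-6)
  # two voids: the largest is measured, with a warning
  img[5:6, 5:6] <- 0.1
  expect_warning(sz2 <- apparent_marker_size(img, g), "largest")
  expect_equal(unname(sz2), c(4, 8) * 1.56, tolerance = 1e-6)
})

test_that("group comparison handles shifts, identity and degenerate input", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1, tolerance = 1e-12)
  shifted <- compare_groups(c(1, 2, 3), c(11, 12, 13))
  ht <- t.test(c(1, 2, 3), c(11, 12, 13))
  expect_equal(shifted$t, unname(ht$statistic))
  expect_equal(shifted$p, ht$p.value)
  expect_equal(shifted$stars, "***")
  expect_equal(compare_groups(c(5, 5), c(5, 5))$p, 1)
  expect_equal(compare_groups(c(5, 5), c(6, 6))$p, 0)
  # star coding thresholds
  star_of <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**"
                          else if (p < 0.05) "*" else ""
  expect_equal(star_of(0.02), "*")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
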