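test_that("the PRF phase coefficient matches the hand-evaluated constant", {
  k <- prf_phase_coefficient(acquisition_params(), 0.0094)
  expect_equal(k, 0.07544, tolerance = 1e-4)
  # 0.07544 rad of phase change is one degree
  acq <- acquisition_params()
  series <- structure(list(
    magnitude = array(1, c(4, 4, 2)),
    phase = array(rep(c(0, 0.07544), each = 16), c(4, 4, 2)),
    times = c(0, 1), orientation = "coronal",
    grid = scan_grid(fov_mm = 6.24, n_rows = 4, n_cols = 4),
    acq = acq, sonication = NULL), class = "image_series")
  tms <- phase_to_temperature(series, reference_frame_index = 1)
  expect_equal(tms$dT[1, 1, 2], 1, tolerance = 1e-4)
  expect_true(all(tms$dT[, , 1] == 0))
})

test_that("noiseless rendering round-trips through PRF conversion exactly", {
  imgs <- mini_images_noiseless()
  f <- mini_field()
  for (ori in c("coronal", "sagittal")) {
    tms <- phase_to_temperature(imgs[[ori]])
    truth <- slab_average(f, ori)
    ns <- dim(truth)[1]
    r0 <- (dim(tms$dT)[1] - ns) %/% 2
    expect_equal(tms$dT[r0 + seq_len(ns), r0 + seq_len(ns), ], truth,
                 tolerance = 1e-10)
    # away from the heated block the maps stay at zero
    expect_equal(max(abs(tms$dT[1:10, , ])), 0, tolerance = 1e-10)
  }
})

test_that("phase-to-temperature is linear in the phase difference", {
  imgs <- mini_images_noiseless()
  ser <- imgs$coronal
  tms1 <- phase_to_temperature(ser)
  ref <- which(ser$times < 3)
  phi_ref <- array(apply(ser$phase[, , ref], c(1, 2), mean), dim(ser$phase))
  # shrink every (wrapped) phase difference by 0.3: dT shrinks by 0.3
  ser$phase <- phi_ref + 0.3 * wrap_phase(ser$phase - phi_ref)
  tms3 <- phase_to_temperature(ser)
  expect_equal(tms3$dT, 0.3 * tms1$dT, tolerance = 1e-8)
})

test_that("temporal averaging reduces noise by sqrt(factor) and keeps means", {
  set.seed(42)
  arr <- array(rnorm(16 * 16 * 40), c(16, 16, 40))
  tms <- structure(list(dT = arr, times = seq(0.5, by = 0.5, length.out = 40),
                        valid = array(TRUE, dim(arr)),
                        grid = scan_grid(fov_mm = 24.96, n_rows = 16,
                                         n_cols = 16),
                        k_rad_per_C = 0.075, alpha = 0.0094,
                        average_factor = 1L, sonication = NULL),
                   class = "thermal_map_series")
  a4 <- temporal_average(tms, 4)
  expect_equal(dim(a4$dT)[3], 10)
  expect_equal(sd(a4$dT) / sd(arr), 0.5, tolerance = 0.05)
  expect_equal(a4$times[1], mean(tms$times[1:4]))
  # identity and constants
  expect_identical(temporal_average(tms, 1), tms)
  tms$dT <- array(7, dim(arr))
  expect_true(all(temporal_average(tms, 4)$dT == 7))
  expect_error(temporal_average(tms, 0), ">= 1")
})

test_that("temporal averaging nearly commutes with PRF conversion", {
  # averaging complex frames weights hot (dimmer) frames slightly less than
  # averaging the converted maps, so commutation holds to ~2% of the peak
  # during the steepest ramp and is exact on static blocks
  imgs <- mini_images_noiseless()
  a <- temporal_average(phase_to_temperature(imgs$coronal), 4)
  ser4 <- temporal_average(imgs$coronal, 4)
  # reference blocks must lie fully before the sonication (a block whose
  # midpoint precedes the delay can still contain heated frames)
  b <- phase_to_temperature(ser4, reference_frame_index =
                              which(ser4$times < 2))
  expect_lt(max(abs(a$dT - b$dT)) / max(a$dT), 0.02)
  # blocks lying fully before the sonication are static: exact there
  pre <- which(a$times < 2)
  expect_equal(a$dT[, , pre], b$dT[, , pre], tolerance = 1e-9)
})

test_that("absorption-correction coefficients normalise to one", {
  mk <- function(val) {
    structure(list(dT = array(val, c(8, 8, 3)), times = c(10, 20, 30),
                   valid = array(TRUE, c(8, 8, 3)),
                   grid = scan_grid(fov_mm = 12.48, n_rows = 8, n_cols = 8),
                   k_rad_per_C = 0.075, alpha = 0.0094, average_factor = 1L,
                   sonication = list(delay_s = 10, duration_s = 20)),
              class = "thermal_map_series")
  }
  corr <- absorption_correction(list(list(mk(29)), list(mk(30)), list(mk(31))))
  expect_equal(unname(round(100 * corr$coefficients, 1)),
               c(96.7, 100, 103.3))
  expect_equal(mean(corr$coefficients), 1, tolerance = 1e-12)
  same <- absorption_correction(list(list(mk(30)), list(mk(30))))
  expect_true(all(same$coefficients == 1))
  expect_error(absorption_correction(list(list(mk(0)), list(mk(0)))),
               "degenerate")
})

test_that("the corrected PRF coefficient equalises phantoms of different absorption", {
  expect_equal(corrected_prf(thermometry_config(), 1), 0.0094)
  expect_error(corrected_prf(thermometry_config(), 0), "> 0")
  # a phantom heating c times more, converted with alpha * c, reports the
  # reference temperature exactly (noiseless)
  imgs <- mini_images_noiseless()
  ref <- phase_to_temperature(imgs$coronal)
  c_hot <- 1.05
  hot <- render_images(scale_heating_field(mini_field(), c_hot), NULL,
                       signal_model(baseline_snr = Inf),
                       acquisition_params(), mini_image_grid(), rng_seed = 1)
  tms_hot <- phase_to_temperature(
    hot$coronal, effective_alpha = corrected_prf(thermometry_config(), c_hot))
  expect_equal(max(tms_hot$dT), max(ref$dT), tolerance = 1e-6)
})

test_that("simulated absorption factors are recovered by the correction", {
  # cohort of 5 phantoms at SNR 50, two reference sonications each
  cohort <- make_phantom_cohort(5, 0.046, rng_seed = 3)
  a <- vapply(cohort, `[[`, numeric(1), "absorption_factor")
  runs <- lapply(seq_along(cohort), function(p) {
    lapply(1:2, function(j) {
      imgs <- render_images(scale_heating_field(mini_field(), a[p]), NULL,
                            signal_model(), acquisition_params(),
                            mini_image_grid(),
                            rng_seed = 100 * p + j,
                            orientations = "coronal")
      temporal_average(phase_to_temperature(imgs$coronal), 4)
    })
  })
  corr <- absorption_correction(runs)
  expect_equal(unname(corr$coefficients), a / mean(a), tolerance = 0.01)
})
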