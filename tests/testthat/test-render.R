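test_that("rendering with no heating and no noise gives flat series", {
  p0 <- sonication_protocol(acoustic_power_W = 0, duration_s = 2,
                            pre_sonication_delay_s = 1, post_observation_s = 2)
  f0 <- simulate_heating(p0, transducer_model(), phantom_spec(), mini_grid3d())
  imgs <- render_images(f0, NULL, signal_model(baseline_snr = Inf),
                        acquisition_params(), mini_image_grid(), rng_seed = 1)
  ph <- imgs$coronal$phase
  expect_equal(max(abs(sweep(ph, c(1, 2), ph[, , 1]))), 0, tolerance = 1e-12)
  expect_true(all(abs(imgs$coronal$magnitude - 1) < 1e-12))
})

test_that("identical seeds render identical noise", {
  a <- render_images(mini_field(), NULL, signal_model(), acquisition_params(),
                     mini_image_grid(), rng_seed = 3, orientations = "coronal")
  b <- render_images(mini_field(), NULL, signal_model(), acquisition_params(),
                     mini_image_grid(), rng_seed = 3, orientations = "coronal")
  expect_identical(a$coronal$magnitude, b$coronal$magnitude)
})

test_that("void profiles share the 50% apparent boundary", {
  for (prof in c("halo", "gaussian")) {
    s <- signal_model(void_profile = prof)
    expect_equal(sonomark:::void_profile_value(1, s), 0.5, tolerance = 0.03)
    expect_lt(sonomark:::void_profile_value(0, s), 0.1)
    expect_gt(sonomark:::void_profile_value(2.5, s), 0.95)
    # monotone non-decreasing in radius
    v <- sonomark:::void_profile_value(seq(0, 2, by = 0.05), s)
    expect_true(all(diff(v) > -1e-9))
  }
  s <- signal_model(void_profile = "hard")
  expect_equal(sonomark:::void_profile_value(c(0.2, 0.99, 1.01), s),
               c(0.05, 0.05, 1))
})

test_that("apparent marker sizes reflect the orientation-dependent factors", {
  p0 <- sonication_protocol(acoustic_power_W = 0, duration_s = 2,
                            pre_sonication_delay_s = 1,
                            post_observation_s = 13)
  f0 <- simulate_heating(p0, transducer_model(), phantom_spec(), mini_grid3d())
  g <- mini_image_grid()
  acq <- acquisition_params()
  measure <- function(marker, ori) {
    imgs <- render_images(f0, marker, signal_model(), acq, g, rng_seed = 9,
                          orientations = ori)
    a32 <- temporal_average(imgs[[ori]], 32)
    apparent_marker_size(a32$magnitude[, , 1], g)
  }
  pitch <- g$in_plane_voxel_mm
  # Visicoil 1.1x10 parallel to B0: apparent width 3.5 mm on the coronal map
  szp <- measure(marker_from_catalogue("Visicoil 1.1x10"), "coronal")
  expect_lt(abs(szp["width_mm"] - 3.5), pitch)
  expect_lt(abs(szp["length_mm"] - 10), pitch)
  # the same marker orthogonal to B0: apparent width 6.5 mm (sagittal map)
  szv <- measure(marker_from_catalogue("Visicoil 1.1x10", "orthogonal_B0"),
                 "sagittal")
  expect_lt(abs(szv["width_mm"] - 6.5), pitch)
  expect_gt(szv["width_mm"], szp["width_mm"])
  # a ball marker gives an isotropic void at width x cohort factor
  szb <- measure(marker_from_catalogue("Gold Anchor 2.1x2.1"), "coronal")
  expect_lt(abs(szb["width_mm"] - 2.1 * 4.2), pitch)
  expect_lt(abs(szb["length_mm"] - 2.1 * 4.2), pitch)
})

test_that("markers below the lattice scale leave no measurable void", {
  p0 <- sonication_protocol(acoustic_power_W = 0, duration_s = 2,
                            pre_sonication_delay_s = 1,
                            post_observation_s = 13)
  f0 <- simulate_heating(p0, transducer_model(), phantom_spec(), mini_grid3d())
  g <- mini_image_grid()
  tiny <- marker_from_catalogue("Visicoil 0.35x5")  # apparent width 1.5 mm
  imgs <- render_images(f0, tiny, signal_model(), acquisition_params(), g,
                        rng_seed = 10, orientations = "coronal")
  a32 <- temporal_average(imgs$coronal, 32)
  sz <- apparent_marker_size(a32$magnitude[, , 1], g)
  expect_equal(unname(sz["width_mm"]), 0)
})
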