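# Shared fixtures, built once per test run and cached. All simulations here
# are miniature (short sonication, ~20 mm cube, 100 mm FOV) so the whole
# suite stays fast; the acceptance tests run the full-length protocol.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

mini_protocol <- function() {
  sonication_protocol(duration_s = 6, pre_sonication_delay_s = 3,
                      post_observation_s = 10)
}

mini_grid3d <- function() sim_grid(20)

mini_image_grid <- function() scan_grid(fov_mm = 100, n_rows = 64, n_cols = 64)

# calibrated mini heating field (map peak 30 degC)
mini_field <- function() {
  cached("mini_field", {
    p <- mini_protocol()
    sc <- calibrate_source(30, p, transducer_model(), phantom_spec(),
                           mini_grid3d())
    simulate_heating(p, transducer_model(source_scale = sc), phantom_spec(),
                     mini_grid3d())
  })
}

# noiseless mini render (both planes)
mini_images_noiseless <- function() {
  cached("mini_images_noiseless",
         render_images(mini_field(), marker = NULL,
                       signal_model(baseline_snr = Inf),
                       acquisition_params(), mini_image_grid(),
                       rng_seed = 1L))
}
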