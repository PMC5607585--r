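# Specifications of the synthetic phantom experiment: sonication protocol,
# transducer focal geometry, per-phantom properties, the MR signal model, and
# the phantom cohort generator.

#' Volumetric sonication protocol
#'
#' The clinical-style pattern studied here: the focal point is swept along
#' concentric inner-outer circles of 3, 6 and 9 mm diameter in a coronal
#' plane at 40 W acoustic power for 30 s. Sonication starts 10 s after the
#' first thermometry frame (so the marker's void can be quantified before any
#' heating) and the maps keep running for 60 s of cooling, which still
#' contributes thermal dose.
#'
#' @param circle_diameters_mm strictly increasing circle diameters in mm.
#' @param acoustic_power_W acoustic power in W.
#' @param duration_s sonication duration in s.
#' @param pre_sonication_delay_s imaging lead-in before the sonication in s.
#' @param post_observation_s cooling observation window in s.
#' @param points_per_circle discrete dwell points per circle (the
#'   discretisation of the swept ring; 32 approximates the continuous sweep
#'   well for a sub-millimetre focus).
#' @param dwell_schedule only `"uniform_sequential"`: each circle's points
#'   are visited uniformly and sequentially, circles inner to outer, each
#'   circle receiving time proportional to its circumference. The pattern
#'   is swept many times per thermal time constant, so the solver uses the
#'   time-averaged deposition of the pattern.
#' @return an object of class `sonication_protocol`.
#' @export
sonication_protocol <- function(circle_diameters_mm = c(3, 6, 9),
                                acoustic_power_W = 40, duration_s = 30,
                                pre_sonication_delay_s = 10,
                                post_observation_s = 60,
                                points_per_circle = 32,
                                dwell_schedule = "uniform_sequential") {
  if (is.unsorted(circle_diameters_mm, strictly = TRUE))
    stop_invalid("circle diameters must be strictly increasing")
  if (any(c(duration_s, pre_sonication_delay_s, post_observation_s) < 0))
    stop_invalid("delay, duration and observation must be >= 0")
  dwell_schedule <- match.arg(dwell_schedule, "uniform_sequential")
  structure(list(circle_diameters_mm = circle_diameters_mm,
                 acoustic_power_W = acoustic_power_W,
                 duration_s = duration_s,
                 pre_sonication_delay_s = pre_sonication_delay_s,
                 post_observation_s = post_observation_s,
                 points_per_circle = as.integer(points_per_circle),
                 dwell_schedule = dwell_schedule),
            class = "sonication_protocol")
}

protocol_total_time <- function(p) {
  p$pre_sonication_delay_s + p$duration_s + p$post_observation_s
}

#' HIFU transducer / focal spot model
#'
#' Only the focal geometry matters for the heating simulation: the deposited
#' power density is a 3D Gaussian whose -6 dB widths match the focal spot
#' (0.7 x 0.7 mm in-plane, 4.5 mm along the beam). `source_scale` converts
#' acoustic power to a heating rate and is normally set by
#' [calibrate_source()].
#'
#' @param focal_widths_mm -6 dB focal widths (x, y, z) in mm; the beam axis
#'   is the z (slice-normal of the coronal plane) direction.
#' @param frequency_MHz operating frequency (informational).
#' @param source_scale heating amplitude per W (degC/s/W at the focus peak).
#' @return an object of class `transducer_model`.
#' @export
transducer_model <- function(focal_widths_mm = c(0.7, 0.7, 4.5),
                             frequency_MHz = 1.45, source_scale = 1) {
  if (any(focal_widths_mm <= 0)) stop_invalid("focal widths must be positive")
  if (source_scale < 0) stop_invalid("source_scale must be >= 0")
  structure(list(focal_widths_mm = focal_widths_mm,
                 frequency_MHz = frequency_MHz,
                 source_scale = source_scale),
            class = "transducer_model")
}

#' Per-phantom physical properties
#'
#' @param absorption_factor relative ultrasound absorption of this phantom's
#'   gel (cohort mean 1). The temperature rise is proportional to it, which
#'   is what the absorption-correction procedure exploits.
#' @param thermal_diffusivity_mm2_s thermal diffusivity in mm^2/s
#'   (soft-tissue-like gel, default 0.14).
#' @param marker a [marker_spec()] embedded at the sonication centre, or
#'   `NULL` for a reference phantom.
#' @param wire_thread whether positioning threads are present
#'   (informational).
#' @param perfusion_rate_per_s perfusion loss rate; gel phantoms are not
#'   perfused so the default is 0 (the hook exists for completeness).
#' @param rng_seed per-phantom seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(absorption_factor = 1,
                         thermal_diffusivity_mm2_s = 0.14,
                         marker = NULL, wire_thread = FALSE,
                         perfusion_rate_per_s = 0, rng_seed = 1L) {
  if (absorption_factor <= 0) stop_invalid("absorption_factor must be > 0")
  if (thermal_diffusivity_mm2_s < 0) stop_invalid("diffusivity must be >= 0")
  if (!is.null(marker)) stopifnot(inherits(marker, "marker_spec"))
  structure(list(absorption_factor = absorption_factor,
                 thermal_diffusivity_mm2_s = thermal_diffusivity_mm2_s,
                 marker = marker, wire_thread = wire_thread,
                 perfusion_rate_per_s = perfusion_rate_per_s,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' MR signal model for image rendering
#'
#' Magnitude follows the spoiled gradient-echo (SPGR) steady state with a
#' temperature-dependent T1: `T1(dT) = baseline_t1 * (1 + 0.01 dT)` (the
#' ~1%/degC T1 increase that makes the signal - and hence the SNR - drop as
#' the phantom heats, coupling the masked-voxel count to the temperature).
#' The marker suppresses magnitude inside its apparent-size ellipsoid.
#'
#' @param baseline_snr background magnitude SNR of a single frame.
#' @param t1_temp_coeff fractional T1 increase per degC (0.01).
#' @param baseline_t1_ms baseline T1 of the agar gel in ms (long, ~1.8 s at
#'   1.5 T for dilute agar).
#' @param void_floor_fraction magnitude fraction remaining at the marker
#'   centre.
#' @param void_profile radial shape of the suppression (all variants reach
#'   50% of background at the apparent-size boundary, so the measured
#'   apparent size is the same): `"halo"` (default) is a deep core
#'   surrounded by a broad marginal-signal skirt at `halo_level_fraction`
#'   of background, emulating the partially dephased rim of a
#'   susceptibility void whose voxels hover around the masking threshold -
#'   the regime in which masked-voxel counts fluctuate frame to frame and
#'   grow with heating; `"gaussian"` is a smooth monotone suppression;
#'   `"hard"` is binary inside the ellipsoid.
#' @param halo_level_fraction skirt magnitude level (halo profile). The
#'   default 0.20 puts the skirt's single-frame temperature noise near
#'   1.9 degC at the default SNR, i.e. marginal against the 2 degC rule
#'   (the regime the masked-count dynamics require).
#' @param core_radius_fraction radius of the deep core as a fraction of the
#'   apparent-size boundary (halo profile).
#' @return an object of class `signal_model`.
#' @export
signal_model <- function(baseline_snr = 50, t1_temp_coeff = 0.01,
                         baseline_t1_ms = 1800, void_floor_fraction = 0.05,
                         void_profile = c("halo", "gaussian", "hard"),
                         halo_level_fraction = 0.20,
                         core_radius_fraction = 0.3) {
  void_profile <- match.arg(void_profile)
  if (baseline_snr <= 0) stop_invalid("baseline_snr must be > 0")
  if (void_floor_fraction < 0 || void_floor_fraction >= 0.5)
    stop_invalid("void_floor_fraction must be in [0, 0.5)")
  if (halo_level_fraction <= void_floor_fraction || halo_level_fraction >= 0.5)
    stop_invalid("halo_level_fraction must lie between the floor and 0.5")
  if (core_radius_fraction <= 0 || core_radius_fraction >= 1)
    stop_invalid("core_radius_fraction must be in (0, 1)")
  structure(list(baseline_snr = baseline_snr, t1_temp_coeff = t1_temp_coeff,
                 baseline_t1_ms = baseline_t1_ms,
                 void_floor_fraction = void_floor_fraction,
                 void_profile = void_profile,
                 halo_level_fraction = halo_level_fraction,
                 core_radius_fraction = core_radius_fraction),
            class = "signal_model")
}

# SPGR steady-state signal (arbitrary units).
spgr_signal <- function(t1_ms, tr_ms, flip_deg) {
  e1 <- exp(-tr_ms / t1_ms)
  f <- flip_deg * pi / 180
  sin(f) * (1 - e1) / (1 - cos(f) * e1)
}

#' Generate a cohort of phantoms with variable absorption
#'
#' Absorption factors are drawn from a normal law (mean 1, sd
#' `absorption_sd`), truncated to \[0.8, 1.2\], emulating the gel-to-gel
#' absorption spread observed across phantoms (100 +/- 4.6%).
#'
#' @param n number of phantoms.
#' @param absorption_sd standard deviation of the absorption factor.
#' @param rng_seed seed.
#' @param markers optional list of length `n` of [marker_spec()] or `NULL`.
#' @return list of [phantom_spec()].
#' @export
make_phantom_cohort <- function(n, absorption_sd = 0.046, rng_seed = 1L,
                                markers = NULL) {
  if (n < 1) stop_invalid("n must be >= 1")
  if (absorption_sd < 0 || absorption_sd >= 1)
    stop_invalid("absorption_sd must be in [0, 1)")
  if (!is.null(markers) && length(markers) != n)
    stop_invalid("markers must have length n")
  set.seed(rng_seed)
  draw_trunc <- function() {
    repeat {
      a <- rnorm(1, mean = 1, sd = absorption_sd)
      if (absorption_sd == 0) a <- 1
      if (a >= 0.8 && a <= 1.2) return(a)
    }
  }
  lapply(seq_len(n), function(i) {
    phantom_spec(absorption_factor = draw_trunc(),
                 marker = if (is.null(markers)) NULL else markers[[i]],
                 rng_seed = derive_seed(rng_seed, i))
  })
}

#' Isotropic simulation grid around the focus
#'
#' A cube of voxel centres at half-integer multiples of the pitch (matching
#' the imaging grid's voxel-corner convention), centred on the sonication
#' centre. Defaults: 1.56 mm spacing over a ~40 mm cube.
#'
#' @param extent_mm cube edge length in mm.
#' @param spacing_mm isotropic voxel spacing in mm.
#' @return an object of class `sim_grid` with axis coordinates `x`, `y`, `z`.
#' @export
sim_grid <- function(extent_mm = 40, spacing_mm = 1.56) {
  n <- 2L * ceiling(extent_mm / (2 * spacing_mm))
  ax <- (seq_len(n) - (n + 1) / 2) * spacing_mm
  structure(list(x = ax, y = ax, z = ax, n = n, spacing_mm = spacing_mm),
            class = "sim_grid")
}
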