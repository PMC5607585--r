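# Synthetic gradient-echo image rendering: PRF phase encoding of the
# simulated temperature, SPGR magnitude with temperature-dependent T1, the
# marker's apparent-size signal void, and complex Gaussian noise.

#' Acquisition parameters of the thermometry sequence
#'
#' Defaults follow the EPI gradient-echo thermometry protocol used here:
#' TE 20 ms, TR 85 ms, flip 20 deg, EPI factor 19, at 1.5 T.
#'
#' @param te_ms echo time (ms).
#' @param tr_ms repetition time (ms).
#' @param flip_deg flip angle (degrees).
#' @param epi_factor EPI factor (informational).
#' @param b0_T main field strength (T).
#' @param gyromagnetic_MHz_per_T proton gyromagnetic ratio (MHz/T).
#' @param frame_interval_s dynamic frame spacing (s).
#' @return an object of class `acquisition_params`.
#' @export
acquisition_params <- function(te_ms = 20, tr_ms = 85, flip_deg = 20,
                               epi_factor = 19, b0_T = 1.5,
                               gyromagnetic_MHz_per_T = 42.576,
                               frame_interval_s = 0.5) {
  vals <- c(te_ms, tr_ms, flip_deg, epi_factor, b0_T,
            gyromagnetic_MHz_per_T, frame_interval_s)
  if (any(vals <= 0)) stop_invalid("acquisition parameters must be positive")
  structure(list(te_ms = te_ms, tr_ms = tr_ms, flip_deg = flip_deg,
                 epi_factor = epi_factor, b0_T = b0_T,
                 gyromagnetic_MHz_per_T = gyromagnetic_MHz_per_T,
                 frame_interval_s = frame_interval_s),
            class = "acquisition_params")
}

#' PRF phase-per-temperature coefficient
#'
#' `k = 2 pi gamma B0 alpha TE` in rad/degC: the phase change produced by a
#' 1 degC temperature rise. With the defaults (TE 20 ms, 1.5 T,
#' alpha 0.0094 ppm/degC) k = 0.07544 rad/degC.
#'
#' @param acq an [acquisition_params()].
#' @param prf_coeff_ppm_per_C PRF coefficient alpha in ppm/degC.
#' @return k in rad/degC.
#' @export
prf_phase_coefficient <- function(acq, prf_coeff_ppm_per_C = 0.0094) {
  stopifnot(inherits(acq, "acquisition_params"))
  2 * pi * acq$gyromagnetic_MHz_per_T * acq$b0_T * prf_coeff_ppm_per_C *
    acq$te_ms * 1e-3
}

# In-plane voxel-centre coordinates of an image axis (mm, origin at the FOV
# centre; voxel-corner convention with even n).
image_axis <- function(n, pitch) (seq_len(n) - n / 2 - 0.5) * pitch

# Radial magnitude-suppression profile of the signal void, evaluated at the
# normalised elliptical radius rho (rho = 1 at the apparent-size boundary).
# Every variant crosses 50% of background at rho = 1 so the measured
# apparent size is profile-independent.
void_profile_value <- function(rho, signal) {
  floorf <- signal$void_floor_fraction
  switch(signal$void_profile,
    hard = ifelse(rho <= 1, floorf, 1),
    gaussian = {
      a <- log((1 - floorf) / 0.5)
      1 - (1 - floorf) * exp(-a * rho^2)
    },
    halo = {
      # deep core -> marginal skirt -> smooth recovery; the outer logistic
      # is centred so the 50% crossing stays at rho = 1
      h <- signal$halo_level_fraction
      w_core <- 0.05
      w_edge <- 0.05
      rho_b <- 1 - w_edge * stats::qlogis((0.5 - h) / (1 - h))
      floorf + (h - floorf) * stats::plogis((rho - signal$core_radius_fraction) / w_core) +
        (1 - h) * stats::plogis((rho - rho_b) / w_edge)
    })
}

# Void multiplier of a marker on an image plane: the apparent-size
# ellipsoid's mid-slice cross-section. The apparent factors were measured on
# images, so slab partial volume is already part of them and the footprint
# is not re-attenuated through the slab.
void_multiplier <- function(marker, signal, grid,
                            orientation = c("coronal", "sagittal")) {
  orientation <- match.arg(orientation)
  if (is.null(marker))
    return(matrix(1, grid$n_rows, grid$n_cols))
  wf <- marker$apparent_width_factor
  lf <- marker$apparent_length_factor
  if (marker$shape == "sphere") {
    s <- rep(marker$width_mm * wf / 2, 3)
  } else {
    half_w <- marker$width_mm * wf / 2
    half_l <- marker$length_mm * lf / 2
    s <- if (marker$orientation == "parallel_B0")
      c(half_w, half_l, half_w) else c(half_w, half_w, half_l)
  }
  pitch <- grid$in_plane_voxel_mm
  u <- image_axis(grid$n_rows, pitch)
  v <- image_axis(grid$n_cols, pitch)
  rho2 <- if (orientation == "coronal")
    outer((u / s[1])^2, (v / s[2])^2, `+`)
  else
    outer((u / s[2])^2, (v / s[3])^2, `+`)
  void_profile_value(sqrt(rho2), signal)
}

#' Render a complex MR image series from a simulated heating field
#'
#' Per frame and per voxel: the temperature of the 5 mm imaging slab is the
#' slab average of the simulated field; the phase is a fixed smooth baseline
#' plus `k * dT` with `k` from [prf_phase_coefficient()]; the magnitude is
#' the SPGR steady-state signal with `T1(dT) = T1_0 (1 + 0.01 dT)`
#' (normalised to 1 at baseline), multiplied by the marker's apparent-size
#' void profile; independent Gaussian noise of sd
#' `1 / baseline_snr` is added to the real and imaginary channels
#' (`baseline_snr = Inf` renders noiseless images).
#'
#' @param field a `heating_field` from [simulate_heating()].
#' @param marker a [marker_spec()] at the sonication centre, or `NULL`.
#' @param signal a [signal_model()].
#' @param acq an [acquisition_params()].
#' @param grid a [scan_grid()] describing the image lattice (shared by both
#'   orientations).
#' @param rng_seed seed for the noise.
#' @param prf_coeff_ppm_per_C PRF coefficient used for phase encoding.
#' @param orientations which planes to render.
#' @return named list of `image_series` objects (fields: `magnitude`,
#'   `phase`, `times`, `orientation`, `grid`, `acq`, `sonication`).
#' @export
render_images <- function(field, marker = NULL, signal = signal_model(),
                          acq = acquisition_params(), grid = scan_grid(),
                          rng_seed = 1L, prf_coeff_ppm_per_C = 0.0094,
                          orientations = c("coronal", "sagittal")) {
  stopifnot(inherits(field, "heating_field"), inherits(grid, "scan_grid"),
            inherits(acq, "acquisition_params"),
            inherits(signal, "signal_model"))
  if (abs(field$grid$spacing_mm - grid$in_plane_voxel_mm) > 1e-9)
    stop_invalid("simulation spacing and image pitch must match")
  ns <- field$grid$n
  if (ns > min(grid$n_rows, grid$n_cols))
    stop_invalid("simulated region larger than the image grid")
  if (ns %% 2L || grid$n_rows %% 2L || grid$n_cols %% 2L)
    stop_invalid("grids must have even sizes (voxel-corner convention)")
  set.seed(rng_seed)
  k <- prf_phase_coefficient(acq, prf_coeff_ppm_per_C)
  s0 <- spgr_signal(signal$baseline_t1_ms, acq$tr_ms, acq$flip_deg)
  sigma <- 1 / signal$baseline_snr
  son <- if (!is.null(field$protocol))
    list(delay_s = field$protocol$pre_sonication_delay_s,
         duration_s = field$protocol$duration_s) else NULL
  out <- list()
  for (ori in orientations) {
    g <- grid; g$orientation <- ori
    dTs <- slab_average(field, ori, grid$slice_thickness_mm)
    nf <- dim(dTs)[3]
    r0 <- (grid$n_rows - ns) %/% 2L
    c0 <- (grid$n_cols - ns) %/% 2L
    u <- image_axis(grid$n_rows, grid$in_plane_voxel_mm) / grid$fov_mm
    v <- image_axis(grid$n_cols, grid$in_plane_voxel_mm) / grid$fov_mm
    phase0 <- outer(0.6 * u, -0.4 * v, `+`) + 0.5 * outer(u, v) + 0.3
    mvoid <- void_multiplier(marker, signal, g, ori)
    mag <- array(0, c(grid$n_rows, grid$n_cols, nf))
    ph <- array(0, c(grid$n_rows, grid$n_cols, nf))
    for (f in seq_len(nf)) {
      dT <- matrix(0, grid$n_rows, grid$n_cols)
      dT[r0 + seq_len(ns), c0 + seq_len(ns)] <- dTs[, , f]
      t1 <- signal$baseline_t1_ms * (1 + signal$t1_temp_coeff * dT)
      m <- (spgr_signal(t1, acq$tr_ms, acq$flip_deg) / s0) * mvoid
      phi <- phase0 + k * dT
      z <- m * exp(1i * phi)
      if (sigma > 0)
        z <- z + complex(real = rnorm(length(z), sd = sigma),
                         imaginary = rnorm(length(z), sd = sigma))
      mag[, , f] <- Mod(z)
      ph[, , f] <- Arg(z)
    }
    out[[ori]] <- structure(list(magnitude = mag, phase = ph,
                                 times = field$times, orientation = ori,
                                 grid = g, acq = acq, sonication = son),
                            class = "image_series")
  }
  out
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %s, %d x %d x %d frames, %.2f mm pitch\n",
              x$orientation, dim(x$magnitude)[1], dim(x$magnitude)[2],
              dim(x$magnitude)[3], x$grid$in_plane_voxel_mm))
  invisible(x)
}
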