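# Packaged marker catalogue, NIfTI + JSON-sidecar image interchange, and
# YAML run configuration.

#' The packaged marker catalogue
#'
#' The 14 markers of the study cohort (Gold Anchor, Visicoil, BiomarC) with
#' physical dimensions, model volumes and apparent-size factors. Apparent
#' factors default to the cohort means (x4.2 width, x2 length); the Visicoil
#' 1.1x10 carries its measured anchors (apparent width 3.5 mm parallel to
#' B0, 6.5 mm orthogonal).
#'
#' @return data frame with one row per marker, including `volume_mm3` from
#'   the cylinder/sphere model.
#' @export
marker_catalogue <- function() {
  path <- system.file("extdata", "marker_catalogue.csv", package = "sonomark")
  cat_df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cat_df$volume_mm3 <- vapply(seq_len(nrow(cat_df)), function(i) {
    marker_model_volume(marker_from_row(cat_df[i, ]))
  }, numeric(1))
  cat_df
}

marker_from_row <- function(row, orientation = "parallel_B0") {
  wf <- row$apparent_width_factor
  if (orientation == "orthogonal_B0" && !is.na(row$orthogonal_width_factor))
    wf <- row$orthogonal_width_factor
  marker_spec(name = row$name, material = row$material, shape = row$shape,
              width_mm = row$width_mm, length_mm = row$length_mm,
              orientation = orientation, apparent_width_factor = wf,
              apparent_length_factor = row$apparent_length_factor)
}

#' Build a marker spec from the packaged catalogue
#'
#' @param name catalogue name, e.g. `"Visicoil 1.1x10"`.
#' @param orientation `"parallel_B0"` or `"orthogonal_B0"`. For markers
#'   whose orthogonal apparent width was not measured, the parallel factor
#'   is reused.
#' @return a [marker_spec()].
#' @export
marker_from_catalogue <- function(name, orientation = c("parallel_B0",
                                                        "orthogonal_B0")) {
  orientation <- match.arg(orientation)
  cat_df <- marker_catalogue()
  i <- match(name, cat_df$name)
  if (is.na(i))
    stop_invalid("marker '%s' not in the catalogue (see marker_catalogue())",
                 name)
  marker_from_row(cat_df[i, ], orientation)
}

nifti_with_pixdim <- function(arr, pixdim) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdim[seq_len(length(dim(arr)))]
  img
}

#' Write an image series as NIfTI volumes plus a JSON sidecar
#'
#' Magnitude and phase go to `<prefix>_mag.nii.gz` / `<prefix>_phase.nii.gz`
#' (4D, mm/s units in pixdim); timing, orientation, grid and acquisition
#' parameters go to `<prefix>.json`.
#'
#' @param series an `image_series`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_image_series <- function(series, prefix) {
  stopifnot(inherits(series, "image_series"))
  g <- series$grid
  dt <- if (length(series$times) > 1) diff(series$times[1:2]) else 1
  pd <- c(g$in_plane_voxel_mm, g$in_plane_voxel_mm, g$slice_thickness_mm, dt)
  pd3 <- c(pd[1], pd[2], dt)
  RNifti::writeNifti(nifti_with_pixdim(series$magnitude, pd3),
                     paste0(prefix, "_mag.nii.gz"))
  RNifti::writeNifti(nifti_with_pixdim(series$phase, pd3),
                     paste0(prefix, "_phase.nii.gz"))
  meta <- list(times = series$times, orientation = series$orientation,
               grid = unclass(series$grid), acq = unclass(series$acq),
               sonication = series$sonication,
               package_version = as.character(utils::packageVersion("sonomark")))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read an image series written by [write_image_series()]
#'
#' @param prefix path prefix used at write time.
#' @return an `image_series`.
#' @export
read_image_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  grid <- do.call(scan_grid, meta$grid)
  acq <- do.call(acquisition_params, meta$acq)
  son <- meta$sonication
  read_arr <- function(path) {
    img <- RNifti::readNifti(path)
    array(as.numeric(img), dim = dim(img))
  }
  structure(list(
    magnitude = read_arr(paste0(prefix, "_mag.nii.gz")),
    phase = read_arr(paste0(prefix, "_phase.nii.gz")),
    times = meta$times, orientation = meta$orientation,
    grid = grid, acq = acq,
    sonication = if (is.null(son)) NULL else as.list(son)),
    class = "image_series")
}

#' Write a thermal-map series (temperature + validity mask) as NIfTI
#'
#' @param tms a `thermal_map_series`.
#' @param prefix output path prefix; writes `<prefix>_dT.nii.gz`,
#'   `<prefix>_valid.nii.gz` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_thermal_maps <- function(tms, prefix) {
  stopifnot(inherits(tms, "thermal_map_series"))
  g <- tms$grid
  dt <- if (length(tms$times) > 1) diff(tms$times[1:2]) else 1
  pd3 <- c(g$in_plane_voxel_mm, g$in_plane_voxel_mm, dt)
  RNifti::writeNifti(nifti_with_pixdim(tms$dT, pd3),
                     paste0(prefix, "_dT.nii.gz"))
  RNifti::writeNifti(nifti_with_pixdim(tms$valid + 0L, pd3),
                     paste0(prefix, "_valid.nii.gz"))
  meta <- list(times = tms$times, alpha = tms$alpha,
               k_rad_per_C = tms$k_rad_per_C,
               average_factor = tms$average_factor,
               grid = unclass(tms$grid),
               package_version = as.character(utils::packageVersion("sonomark")))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

# ---- run configuration ------------------------------------------------------

run_config_defaults <- function() {
  list(
    protocol = list(circle_diameters_mm = c(3, 6, 9), acoustic_power_W = 40,
                    duration_s = 30, pre_sonication_delay_s = 10,
                    post_observation_s = 60, points_per_circle = 32),
    transducer = list(focal_widths_mm = c(0.7, 0.7, 4.5),
                      frequency_MHz = 1.45, source_scale = NULL),
    acquisition = list(te_ms = 20, tr_ms = 85, flip_deg = 20, epi_factor = 19,
                       b0_T = 1.5, gyromagnetic_MHz_per_T = 42.576,
                       frame_interval_s = 0.5),
    thermometry = list(prf_coeff_ppm_per_C = 0.0094,
                       temporal_average_factor = 4,
                       display_average_factor = 32),
    masking = list(sigma_threshold_C = 2, averaged_sigma_threshold_C = 1,
                   majority_fraction = 0.5, neighborhood = 8),
    dose = list(baseline_temp_C = 37, threshold_EM = 240, breakpoint_C = 43,
                R_above = 0.5, R_below = 0.25, reconstruction_grid_mm = 1.56,
                reconstruction_extent_mm = 40),
    signal = list(baseline_snr = 50, t1_temp_coeff = 0.01,
                  baseline_t1_ms = 1800, void_floor_fraction = 0.05,
                  void_profile = "halo", halo_level_fraction = 0.20,
                  core_radius_fraction = 0.3),
    phantom = list(thermal_diffusivity_mm2_s = 0.14, absorption_sd = 0.046),
    image = list(fov_mm = 200, in_plane_voxel_mm = 1.56,
                 slice_thickness_mm = 5, n_rows = 128, n_cols = 128),
    simulation = list(grid_extent_mm = 40, spacing_mm = 1.56,
                      time_step_s = 0.05, calibration_peak_C = 30),
    study = list(markers = list("Gold Anchor 2.1x2.1", "Visicoil 1.1x10"),
                 n_on_marker = 6, n_reference = 6, seed = 1)
  )
}

merge_config <- function(defaults, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop_invalid("unknown configuration key '%s'", here)
    dv <- defaults[[key]]
    ov <- override[[key]]
    if (is.list(dv) && !is.null(names(dv)) && is.list(ov)) {
      defaults[[key]] <- merge_config(dv, ov, here)
    } else if (is.null(ov)) {
      defaults[key] <- list(NULL)
    } else {
      defaults[[key]] <- ov
    }
  }
  defaults
}

#' Build a run configuration
#'
#' Returns the full study configuration with defaults (the parameter values
#' of the phantom study: TE 20 ms, alpha 0.0094 ppm/degC, 240 EM threshold,
#' 3/6/9 mm circles at 40 W for 30 s, ...) overridden by the supplied named
#' sections. Unknown keys are rejected with their path.
#'
#' @param ... named sections (e.g. `study = list(seed = 7)`).
#' @return a plain nested list of class `run_config` (YAML-serialisable).
#' @export
run_config <- function(...) {
  override <- list(...)
  cfg <- merge_config(run_config_defaults(), override)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; its keys override the defaults and unknown keys
#'   are rejected by name.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' Save a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
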