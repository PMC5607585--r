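# Masked-voxel identification and quantification. A voxel is "masked" when
# its magnitude SNR is too low for reliable phase-based thermometry: the
# temperature standard deviation sigma_T = sqrt(2) / (SNR * k) exceeds
# 2 degC on unaveraged frames (1 degC after x4 temporal averaging). The
# sqrt(2) accounts for the phase difference of two noisy frames.

#' Masking configuration
#'
#' @param sigma_threshold_C sigma_T threshold on unaveraged frames (2 degC).
#' @param averaged_sigma_threshold_C equivalent threshold after x4 temporal
#'   averaging (1 degC).
#' @param majority_fraction a voxel enters the majority mask when masked in
#'   strictly more than this fraction of the frames (0.5).
#' @param noise_sigma_estimate magnitude noise sd; `NULL` to estimate from a
#'   background corner of the images.
#' @param neighborhood infill neighbourhood, 4- or 8-connected (in-plane).
#' @return an object of class `masking_config`.
#' @export
masking_config <- function(sigma_threshold_C = 2,
                           averaged_sigma_threshold_C = 1,
                           majority_fraction = 0.5,
                           noise_sigma_estimate = NULL,
                           neighborhood = c(8, 4)) {
  neighborhood <- as.integer(neighborhood[1])
  if (!neighborhood %in% c(4L, 8L)) stop_invalid("neighborhood must be 4 or 8")
  if (sigma_threshold_C <= 0 || averaged_sigma_threshold_C <= 0)
    stop_invalid("sigma thresholds must be > 0")
  if (majority_fraction <= 0 || majority_fraction >= 1)
    stop_invalid("majority_fraction must be in (0, 1)")
  structure(list(sigma_threshold_C = sigma_threshold_C,
                 averaged_sigma_threshold_C = averaged_sigma_threshold_C,
                 majority_fraction = majority_fraction,
                 noise_sigma_estimate = noise_sigma_estimate,
                 neighborhood = neighborhood),
            class = "masking_config")
}

#' Estimate the magnitude noise sd from background corners
#'
#' Robust sd (MAD) of the magnitude in the four image corner blocks, pooled
#' over frames. At high SNR the magnitude noise sd equals the per-channel
#' complex noise sd.
#'
#' @param series an `image_series` (or a magnitude array).
#' @param block corner block size in voxels.
#' @return estimated noise sd (magnitude units).
#' @export
estimate_noise_sigma <- function(series, block = 8L) {
  mag <- if (inherits(series, "image_series")) series$magnitude else series
  if (length(dim(mag)) == 2) dim(mag) <- c(dim(mag), 1)
  nr <- dim(mag)[1]; nc <- dim(mag)[2]
  b <- min(block, nr %/% 4L, nc %/% 4L)
  vals <- c(mag[1:b, 1:b, ], mag[1:b, (nc - b + 1):nc, ],
            mag[(nr - b + 1):nr, 1:b, ], mag[(nr - b + 1):nr, (nc - b + 1):nc, ])
  stats::mad(vals)
}

#' Per-voxel temperature standard deviation map
#'
#' `sigma_T = sqrt(2) / (SNR * k)` with `SNR = magnitude / noise_sigma` and
#' `k` the PRF phase coefficient at the effective alpha. The sqrt(2) factor
#' reflects that a temperature value is the difference of two noisy phase
#' measurements (current frame minus reference).
#'
#' @param magnitude magnitude map (matrix) or array of maps.
#' @param noise_sigma magnitude noise sd (> 0).
#' @param acq an [acquisition_params()].
#' @param effective_alpha PRF coefficient in ppm/degC.
#' @return sigma_T in degC, same shape as `magnitude`.
#' @export
temperature_std_map <- function(magnitude, noise_sigma,
                                acq = acquisition_params(),
                                effective_alpha = 0.0094) {
  if (is.null(noise_sigma) || noise_sigma <= 0)
    stop_invalid("noise_sigma must be a positive magnitude sd")
  k <- prf_phase_coefficient(acq, effective_alpha)
  sqrt(2) * noise_sigma / (magnitude * k)
}

#' Mask a frame by its temperature standard deviation
#'
#' @param sigma_map sigma_T map from [temperature_std_map()].
#' @param threshold_C masking threshold in degC; voxels with
#'   `sigma_T > threshold` are masked.
#' @return logical mask, same shape.
#' @export
mask_frame <- function(sigma_map, threshold_C = 2) {
  sigma_map > threshold_C
}

#' Majority mask over frames
#'
#' A voxel is included iff it is masked in strictly more than
#' `majority_fraction` of the frames (a voxel masked in exactly half of an
#' even number of frames is excluded).
#'
#' @param masks logical array (row, col, frame) or list of logical matrices.
#' @param majority_fraction the strict fraction (default one half).
#' @return logical matrix.
#' @export
majority_mask <- function(masks, majority_fraction = 0.5) {
  if (is.list(masks)) masks <- simplify2array(masks)
  if (is.null(dim(masks))) dim(masks) <- c(1, 1, length(masks))
  if (length(dim(masks)) == 2) dim(masks) <- c(dim(masks), 1)
  nf <- dim(masks)[3]
  if (nf < 1) stop_invalid("majority_mask needs at least one frame")
  rowMeans(masks, dims = 2) > majority_fraction
}

neighbor_shifts <- function(neighborhood) {
  if (neighborhood == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
}

#' Replace masked voxels by the mean of their valid neighbours
#'
#' Masked voxels are filled with the arithmetic mean of their valid in-plane
#' neighbours; voxels with no valid neighbour are filled iteratively from
#' already-filled ones until none remain. Unmasked voxels are returned
#' bit-exact.
#'
#' @param map numeric matrix (e.g. a temperature map).
#' @param mask logical matrix of masked voxels.
#' @param neighborhood 4- or 8-connected (default 8; slices are 5 mm thick,
#'   so infilling stays in-plane).
#' @return the infilled matrix.
#' @export
infill_masked <- function(map, mask, neighborhood = 8L) {
  stopifnot(identical(dim(map), dim(mask)))
  if (all(mask)) stop_invalid("cannot infill a fully masked map")
  if (!any(mask)) return(map)
  shifts <- neighbor_shifts(as.integer(neighborhood))
  valid <- !mask
  vals <- map
  vals[mask] <- 0
  remaining <- mask
  while (any(remaining)) {
    num <- matrix(0, nrow(map), ncol(map))
    den <- matrix(0, nrow(map), ncol(map))
    for (s in shifts) {
      # replicated edges contribute the masked voxel itself at borders,
      # which is harmless: its validity (and value) are zero until filled
      num <- num + shift_mat(vals * valid, s[1], s[2])
      den <- den + shift_mat(valid + 0, s[1], s[2])
    }
    fill <- remaining & den > 0
    if (!any(fill)) stop_invalid("infill failed to progress")
    vals[fill] <- num[fill] / den[fill]
    valid[fill] <- TRUE
    remaining[fill] <- FALSE
  }
  vals
}

#' Masked-voxel report for one sonication
#'
#' Summarises per-frame masked-voxel counts, the strict-majority mask, the
#' masked volume (count x voxel volume), its ratio to the marker's model
#' volume, and the growth factor of the count between the first and last
#' frame (the count grows during heating because the T1-driven signal decay
#' lowers the SNR).
#'
#' @param masks logical array (row, col, frame) of per-frame masks.
#' @param grid a [scan_grid()].
#' @param marker a [marker_spec()] (its model volume must be positive).
#' @param majority_fraction strict majority fraction.
#' @return an object of class `mask_report`: `per_frame_counts`,
#'   `majority_mask`, `majority_count`, `masked_volume_mm3`,
#'   `ratio_to_marker_volume`, `growth_factor` (NA when the first-frame
#'   count is zero).
#' @export
mask_report <- function(masks, grid, marker, majority_fraction = 0.5) {
  stopifnot(inherits(grid, "scan_grid"), inherits(marker, "marker_spec"))
  mv <- marker_model_volume(marker)
  if (mv <= 0) stop_invalid("marker model volume must be positive")
  if (is.list(masks)) masks <- simplify2array(masks)
  counts <- apply(masks, 3, sum)
  mm <- majority_mask(masks, majority_fraction)
  vol <- sum(mm) * voxel_volume(grid)
  growth <- if (counts[1] > 0) counts[length(counts)] / counts[1] else NA_real_
  structure(list(per_frame_counts = as.integer(counts), majority_mask = mm,
                 majority_count = sum(mm), masked_volume_mm3 = vol,
                 ratio_to_marker_volume = vol / mv, growth_factor = growth,
                 orientation = grid$orientation, marker_name = marker$name),
            class = "mask_report")
}

#' @export
print.mask_report <- function(x, ...) {
  cat(sprintf("<mask_report> %s (%s): majority count %d, volume %.1f mm3, ratio %.1f, growth %s\n",
              x$marker_name, x$orientation, x$majority_count,
              x$masked_volume_mm3, x$ratio_to_marker_volume,
              ifelse(is.na(x$growth_factor), "NA",
                     sprintf("%.2f", x$growth_factor))))
  invisible(x)
}
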