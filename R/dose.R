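# CEM43 thermal dose, two-plane 3D reconstruction, dose volumetry, and the
# per-sonication summary metrics (max unmasked rise, edge-annulus mean,
# apparent marker size, group comparisons).

#' Thermal-dose configuration
#'
#' Cumulative equivalent minutes at 43 degC (CEM43) with the standard
#' piecewise base: `dose = sum_i R^(43 - T_i) dt_i` with `R = 0.5` at or
#' above the 43 degC breakpoint and `0.25` below. Although the phantom sits
#' at room temperature, doses are computed from a 37 degC baseline to mimic
#' the in-vivo situation, and 240 EM is the ablation threshold.
#'
#' @param baseline_temp_C baseline absolute temperature added to the
#'   measured rise (37).
#' @param threshold_EM ablation dose threshold in equivalent minutes (240).
#' @param breakpoint_C CEM43 breakpoint (43).
#' @param R_above,R_below base R at/above and below the breakpoint.
#' @param reconstruction_grid_mm isotropic spacing of the 3D reconstruction
#'   grid (1.56).
#' @param reconstruction_extent_mm edge length of the reconstruction cube
#'   around the focus (40).
#' @return an object of class `dose_config`.
#' @export
dose_config <- function(baseline_temp_C = 37, threshold_EM = 240,
                        breakpoint_C = 43, R_above = 0.5, R_below = 0.25,
                        reconstruction_grid_mm = 1.56,
                        reconstruction_extent_mm = 40) {
  if (!(R_below > 0 && R_below <= R_above && R_above < 1))
    stop_invalid("require 0 < R_below <= R_above < 1")
  if (threshold_EM <= 0) stop_invalid("threshold must be > 0")
  structure(list(baseline_temp_C = baseline_temp_C,
                 threshold_EM = threshold_EM, breakpoint_C = breakpoint_C,
                 R_above = R_above, R_below = R_below,
                 reconstruction_grid_mm = reconstruction_grid_mm,
                 reconstruction_extent_mm = reconstruction_extent_mm),
            class = "dose_config")
}

#' Accumulate CEM43 thermal dose
#'
#' `dose = sum_i R^(43 - T_i) * dt_i` (minutes) per voxel, with
#' `T_i = baseline + dT_i`. Accumulation runs over all supplied frames,
#' i.e. the sonication plus the cooling window, which still contributes
#' dose. Monotone: raising any temperature sample never decreases the dose.
#'
#' @param dT temperature-rise series: array with frames on the last margin
#'   (planar `[r, c, t]` or volumetric `[x, y, z, t]`), or a
#'   `thermal_map_series`.
#' @param frame_interval_s frame spacing in seconds.
#' @param config a [dose_config()].
#' @return dose array (equivalent minutes at 43 degC) with the spatial
#'   dimensions of the input.
#' @export
cem43 <- function(dT, frame_interval_s, config = dose_config()) {
  if (frame_interval_s < 0) stop_invalid("frame interval must be >= 0")
  if (inherits(dT, "thermal_map_series")) dT <- dT$dT
  dm <- dim(dT)
  nd <- length(dm)
  spatial <- dm[-nd]
  m <- matrix(dT, nrow = prod(spatial), ncol = dm[nd])
  temp <- config$baseline_temp_C + m
  R <- ifelse(temp >= config$breakpoint_C, config$R_above, config$R_below)
  dose <- rowSums(R^(config$breakpoint_C - temp)) * frame_interval_s / 60
  array(dose, spatial)
}

#' Two-plane 3D temperature reconstruction (normalized product)
#'
#' Combines an infilled coronal map `Tc(x, y)` and sagittal map `Ts(y, z)`
#' sharing the y axis through the focus into
#' `T(x, y, z) = Tc(x, y) * Ts(y, z) / max(Tline(y), eps)`, with `Tline` the
#' mean of the two planes' profiles along the shared line and `eps` guarding
#' small denominators; output is clamped to `[0, max(Tc, Ts)]`. The scheme
#' is exact for separable fields and serves as the documented deterministic
#' stand-in for the scanner's unpublished reconstruction; outputs carry a
#' `reconstruction = "normalized_product"` attribute.
#'
#' @param coronal matrix `[x, y]`.
#' @param sagittal matrix `[y, z]` with `ncol(coronal) == nrow(sagittal)`.
#' @param eps_fraction `eps` as a fraction of the line profile's maximum.
#' @param mismatch_tol relative mismatch between the two planes' shared-line
#'   profiles above which a consistency warning (not an error) is raised.
#' @param min_peak_for_check line-profile peak below which the consistency
#'   check is skipped (a relative mismatch on near-zero maps is
#'   meaningless; in degC for temperature maps).
#' @return 3D array `[x, y, z]`.
#' @export
reconstruct_3d <- function(coronal, sagittal, eps_fraction = 0.05,
                           mismatch_tol = 0.2, min_peak_for_check = 1) {
  if (ncol(coronal) != nrow(sagittal))
    stop_invalid("planes do not share the y axis (%d vs %d)",
                 ncol(coronal), nrow(sagittal))
  nx <- nrow(coronal); ny <- ncol(coronal); nz <- ncol(sagittal)
  # profiles along the shared line, taken at the row/column nearest the
  # focal centre of each plane
  lc <- coronal[nx %/% 2L, ]
  ls <- sagittal[, nz %/% 2L]
  line <- (lc + ls) / 2
  peak <- max(abs(line))
  if (peak > min_peak_for_check) {
    mism <- max(abs(lc - ls)) / peak
    if (mism > mismatch_tol)
      warning(sprintf("shared-line profiles disagree by %.0f%%", 100 * mism))
  }
  eps <- max(eps_fraction * peak, .Machine$double.eps)
  den <- pmax(line, eps)
  out <- array(0, c(nx, ny, nz))
  for (j in seq_len(ny))
    out[, j, ] <- outer(coronal[, j], sagittal[j, ]) / den[j]
  hi <- max(max(coronal), max(sagittal))
  out[out < 0] <- 0
  out[out > hi] <- hi
  attr(out, "reconstruction") <- "normalized_product"
  out
}

#' Dose volume above a threshold
#'
#' Counts voxels with dose strictly above the threshold and converts to ml.
#'
#' @param dose dose array from [cem43()].
#' @param voxel_volume_mm3 volume of one voxel in mm^3 (e.g. `1.56^3` on the
#'   isotropic reconstruction grid).
#' @param threshold_EM dose threshold (default 240 EM).
#' @return volume in ml.
#' @export
dose_volume <- function(dose, voxel_volume_mm3, threshold_EM = 240) {
  sum(dose > threshold_EM) * voxel_volume_mm3 / 1000
}

#' Maximum temperature rise over unmasked voxels
#'
#' The largest rise over all frames and voxels whose temperature standard
#' deviation passes the masking rule appropriate to the averaging state of
#' the series (2 degC unaveraged, 1 degC after x4 averaging).
#'
#' @param tms a `thermal_map_series`.
#' @param sigma_maps sigma_T array aligned with `tms$dT` (or a single map).
#' @param config a [masking_config()].
#' @return maximum rise in degC.
#' @export
max_unmasked_temperature <- function(tms, sigma_maps,
                                     config = masking_config()) {
  stopifnot(inherits(tms, "thermal_map_series"))
  thr <- if (tms$average_factor >= 4) config$averaged_sigma_threshold_C
         else config$sigma_threshold_C
  if (length(dim(sigma_maps)) == 2)
    sigma_maps <- array(sigma_maps, dim(tms$dT))
  ok <- sigma_maps <= thr
  if (!any(ok)) stop_invalid("all voxels masked; no temperature available")
  max(tms$dT[ok])
}

#' Mean temperature rise over the edge annulus of the targeted region
#'
#' Averages the rise over the voxels whose centres lie between the outer
#' sonication circle (9 mm diameter) and the nominal ablated diameter
#' (12 mm): 28 voxels on the 1.56 mm grid.
#'
#' @param dT_map temperature-rise matrix on the image grid (focus at the
#'   FOV centre).
#' @param grid a [scan_grid()].
#' @param inner_diameter_mm,outer_diameter_mm annulus diameters in mm.
#' @return mean rise in degC.
#' @export
edge_mean_temperature <- function(dT_map, grid, inner_diameter_mm = 9,
                                  outer_diameter_mm = 12) {
  stopifnot(inherits(grid, "scan_grid"))
  reg <- region_spec("annulus", outer_diameter_mm = outer_diameter_mm,
                     inner_diameter_mm = inner_diameter_mm)
  vox <- voxel_centers_in_region(grid, reg)
  if (!nrow(vox)) stop_invalid("edge annulus contains no voxel")
  r <- vox$ix + nrow(dT_map) %/% 2L + 1L
  c <- vox$iy + ncol(dT_map) %/% 2L + 1L
  if (any(r < 1 | r > nrow(dT_map) | c < 1 | c > ncol(dT_map)))
    stop_invalid("edge annulus extends outside the map")
  mean(dT_map[cbind(r, c)])
}

#' Measure the apparent size of a marker's signal void
#'
#' On a heavily averaged magnitude image (x32), the void is the connected
#' set of voxels below 50% of the background level; its width and length are
#' the extents (plus one voxel pitch) of the void along the principal axes
#' through its centroid. Returns `(0, 0)` when no voxel is below the level;
#' with several disjoint voids the largest is measured, with a warning.
#'
#' @param magnitude averaged magnitude image (matrix).
#' @param grid a [scan_grid()].
#' @param background_level background magnitude; `NULL` for the image
#'   median.
#' @return named numeric: `width_mm` (minor extent), `length_mm` (major
#'   extent).
#' @export
apparent_marker_size <- function(magnitude, grid, background_level = NULL) {
  stopifnot(inherits(grid, "scan_grid"))
  bg <- background_level %||% median(magnitude)
  void <- magnitude < 0.5 * bg
  if (!any(void)) return(c(width_mm = 0, length_mm = 0))
  lab <- label_components(void)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) > 1)
    warning("multiple disjoint voids; measuring the largest")
  sel <- lab == which.max(sizes)
  idx <- which(sel, arr.ind = TRUE)
  pitch <- grid$in_plane_voxel_mm
  pts <- cbind(idx[, 1] * pitch, idx[, 2] * pitch)
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  if (nrow(pts) == 1) {
    ext <- c(pitch, pitch)
  } else {
    ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors
    proj <- pts %*% ev
    ext <- apply(proj, 2, function(p) diff(range(p))) + pitch
  }
  c(width_mm = min(ext), length_mm = max(ext))
}

#' Welch two-sample comparison with significance stars
#'
#' Two-sided unequal-variance t-test of a per-sonication metric between a
#' marker phantom and the reference phantom. Stars encode p < 0.05 / 0.01 /
#' 0.001. When both groups are constant: p = 1 (t = 0) for equal means, and
#' p = 0 (infinite t) otherwise, by convention.
#'
#' @param a,b numeric metric values of the two groups (each length >= 2).
#' @return list with `t`, `p`, `stars`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      t <- 0; p <- 1
    } else {
      t <- Inf * sign(mean(a) - mean(b)); p <- 0
    }
  } else {
    ht <- t.test(a, b, var.equal = FALSE)
    t <- unname(ht$statistic); p <- ht$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else ""
  list(t = t, p = p, stars = stars, mean_a = mean(a), mean_b = mean(b))
}
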