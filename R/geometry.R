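# Grids, regions and the closed-form geometric models used throughout:
# marker volumes, the targeted-region ellipsoid, voxel counting in discs and
# annuli, and the volume-ratio <-> diameter-change translation.

#' Imaging grid description
#'
#' Describes the in-plane acquisition grid of the thermometry sequence:
#' 200 mm field of view at 1.56 x 1.56 mm in-plane resolution and 5 mm slice
#' thickness by default. With an even number of columns the centre of the
#' field of view falls on a voxel corner, so voxel centres sit at
#' half-integer multiples of the pitch from the sonication centre
#' (`center_convention = "voxel_corner"`).
#'
#' @param fov_mm field of view in mm.
#' @param in_plane_voxel_mm in-plane voxel pitch in mm.
#' @param slice_thickness_mm slice thickness in mm.
#' @param n_rows,n_cols grid size in voxels.
#' @param orientation `"coronal"` or `"sagittal"`.
#' @param center_convention `"voxel_corner"` (default) or `"voxel_center"`:
#'   where the region/sonication centre falls relative to the voxel lattice.
#' @return an object of class `scan_grid`.
#' @export
scan_grid <- function(fov_mm = 200, in_plane_voxel_mm = 1.56,
                      slice_thickness_mm = 5, n_rows = 128, n_cols = 128,
                      orientation = c("coronal", "sagittal"),
                      center_convention = c("voxel_corner", "voxel_center")) {
  orientation <- match.arg(orientation)
  center_convention <- match.arg(center_convention)
  if (in_plane_voxel_mm <= 0 || slice_thickness_mm <= 0)
    stop_invalid("voxel dimensions must be strictly positive")
  if (abs(fov_mm - n_cols * in_plane_voxel_mm) > in_plane_voxel_mm)
    stop_invalid("fov_mm (%.2f) inconsistent with n_cols * pitch (%.2f)",
                 fov_mm, n_cols * in_plane_voxel_mm)
  structure(list(fov_mm = fov_mm, in_plane_voxel_mm = in_plane_voxel_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 n_rows = n_rows, n_cols = n_cols,
                 orientation = orientation,
                 center_convention = center_convention),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid> %s, %d x %d voxels, %.2f x %.2f x %.1f mm, FOV %g mm (%s)\n",
              x$orientation, x$n_rows, x$n_cols, x$in_plane_voxel_mm,
              x$in_plane_voxel_mm, x$slice_thickness_mm, x$fov_mm,
              x$center_convention))
  invisible(x)
}

# in-plane voxel area / voxel volume in mm^2 / mm^3
voxel_area <- function(grid) grid$in_plane_voxel_mm^2
voxel_volume <- function(grid) grid$in_plane_voxel_mm^2 * grid$slice_thickness_mm

#' Physical description of a biopsy marker
#'
#' A marker is modelled as a cylinder (width = diameter, length = axis) or a
#' sphere (ball-configured markers; width equals length). The apparent-size
#' factors describe how much larger the marker's signal void appears on the
#' thermal maps than its physical size, which depends on material and on the
#' orientation relative to B0.
#'
#' @param name display name, e.g. `"Visicoil 1.1x10"`.
#' @param material one of `"gold"`, `"gold_iron"`, `"brass"`, `"carbon_coated"`.
#' @param shape `"cylinder"` or `"sphere"`.
#' @param width_mm,length_mm physical dimensions in mm.
#' @param orientation long-axis orientation: `"parallel_B0"` (foot-head) or
#'   `"orthogonal_B0"` (anterior-posterior, the worst case for the artifact).
#' @param apparent_width_factor,apparent_length_factor ratio of apparent
#'   (signal-void) size on thermal maps to the physical size; cohort means
#'   are 4.2 (width) and 2 (length).
#' @return an object of class `marker_spec`.
#' @export
marker_spec <- function(name, material = c("gold", "gold_iron", "brass",
                                           "carbon_coated"),
                        shape = c("cylinder", "sphere"),
                        width_mm, length_mm,
                        orientation = c("parallel_B0", "orthogonal_B0"),
                        apparent_width_factor = 4.2,
                        apparent_length_factor = 2) {
  material <- match.arg(material)
  shape <- match.arg(shape)
  orientation <- match.arg(orientation)
  if (width_mm <= 0 || length_mm <= 0)
    stop_invalid("marker dimensions must be positive")
  if (width_mm < 0.28 || width_mm > 2.1)
    stop_invalid("marker width %.2f mm outside the supported 0.28-2.1 mm range",
                 width_mm)
  if (shape == "cylinder" && (length_mm < 3 || length_mm > 30))
    stop_invalid("cylinder length %.1f mm outside the supported 3-30 mm range",
                 length_mm)
  if (shape == "sphere" && !isTRUE(all.equal(width_mm, length_mm)))
    stop_invalid("a spherical marker requires width_mm == length_mm")
  if (apparent_width_factor < 1 || apparent_length_factor < 1)
    stop_invalid("apparent-size factors must be >= 1")
  structure(list(name = name, material = material, shape = shape,
                 width_mm = width_mm, length_mm = length_mm,
                 orientation = orientation,
                 apparent_width_factor = apparent_width_factor,
                 apparent_length_factor = apparent_length_factor),
            class = "marker_spec")
}

#' @export
print.marker_spec <- function(x, ...) {
  cat(sprintf("<marker_spec> %s: %s %s %.2f x %.1f mm, %s, apparent x%.2f/x%.2f\n",
              x$name, x$material, x$shape, x$width_mm, x$length_mm,
              x$orientation, x$apparent_width_factor, x$apparent_length_factor))
  invisible(x)
}

#' In-plane / volumetric region of interest
#'
#' @param kind `"disc"`, `"annulus"` or `"ellipsoid"`.
#' @param outer_diameter_mm outer diameter (disc/annulus) in mm.
#' @param inner_diameter_mm inner diameter (annulus only) in mm.
#' @param axes_mm three diameters in mm (ellipsoid only).
#' @param center region centre in mm coordinates (defaults to the origin,
#'   i.e. the sonication centre).
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(kind = c("disc", "annulus", "ellipsoid"),
                        outer_diameter_mm = NULL, inner_diameter_mm = NULL,
                        axes_mm = NULL, center = c(0, 0)) {
  kind <- match.arg(kind)
  if (kind %in% c("disc", "annulus")) {
    if (is.null(outer_diameter_mm) || outer_diameter_mm < 0)
      stop_invalid("outer_diameter_mm must be a non-negative length")
    if (kind == "annulus") {
      if (is.null(inner_diameter_mm) || inner_diameter_mm < 0)
        stop_invalid("annulus requires a non-negative inner_diameter_mm")
      if (inner_diameter_mm > outer_diameter_mm)
        stop_invalid("annulus requires inner < outer diameter")
    }
  } else {
    if (is.null(axes_mm) || length(axes_mm) != 3 || any(axes_mm < 0))
      stop_invalid("ellipsoid requires three non-negative axes_mm")
  }
  structure(list(kind = kind, outer_diameter_mm = outer_diameter_mm,
                 inner_diameter_mm = inner_diameter_mm, axes_mm = axes_mm,
                 center = center),
            class = "region_spec")
}

#' Model volume of a marker
#'
#' Cylinder model `pi (w/2)^2 L`, or sphere model `(pi/6) w^3` for
#' ball-configured markers.
#'
#' @param spec a [marker_spec()].
#' @return volume in mm^3 (full precision; round to 2 decimals for display).
#' @examples
#' round(marker_model_volume(marker_spec("BiomarC 2x4", "carbon_coated",
#'   "cylinder", 2, 4)), 2)  # 12.57
#' @export
marker_model_volume <- function(spec) {
  stopifnot(inherits(spec, "marker_spec"))
  if (spec$shape == "cylinder")
    pi * (spec$width_mm / 2)^2 * spec$length_mm
  else
    (pi / 6) * spec$width_mm^3
}

#' Ellipsoid volume from its three diameters
#'
#' `(pi/6) a b c`, converted from mm^3 to ml. The nominal targeted/ablated
#' region of the sonication pattern used here is the 12 x 12 x 8 mm
#' ellipsoid, i.e. 0.6 ml.
#'
#' @param axes_mm three diameters in mm.
#' @return volume in ml (full precision).
#' @export
ellipsoid_volume <- function(axes_mm) {
  if (length(axes_mm) != 3 || any(axes_mm < 0))
    stop_invalid("ellipsoid_volume needs three non-negative diameters")
  (pi / 6) * prod(axes_mm) / 1000
}

# Voxel-centre offsets along one axis for a given convention, covering radius
# rmax. voxel_corner: centres at (k + 1/2) * pitch; voxel_center: k * pitch.
center_offsets <- function(pitch, rmax, convention) {
  k <- ceiling(rmax / pitch) + 1L
  if (convention == "voxel_corner")
    (seq(-k, k - 1L) + 0.5) * pitch
  else
    seq(-k, k) * pitch
}

#' Voxels whose centres fall inside a disc or annulus
#'
#' Counts voxel centres with radial distance `inner/2 < r <= outer/2`
#' (annulus; strict inner, inclusive outer) or `r <= d/2` (disc), with the
#' grid's centre convention. With the 1.56 mm pitch and the voxel-corner
#' convention, the 9 -> 12 mm edge annulus contains exactly 28 voxels.
#'
#' @param grid a [scan_grid()].
#' @param region a disc or annulus [region_spec()].
#' @return data frame with columns `ix`, `iy` (signed voxel offsets from the
#'   region centre), `x_mm`, `y_mm` (centre coordinates relative to the
#'   region centre) and `r_mm`.
#' @export
voxel_centers_in_region <- function(grid, region) {
  stopifnot(inherits(grid, "scan_grid"), inherits(region, "region_spec"))
  if (region$kind == "ellipsoid")
    stop_invalid("in-plane voxel counting is defined for disc/annulus regions")
  outer <- region$outer_diameter_mm
  if (outer > grid$fov_mm)
    stop_invalid("region diameter %.1f mm exceeds the %g mm field of view",
                 outer, grid$fov_mm)
  off <- center_offsets(grid$in_plane_voxel_mm, outer / 2,
                        grid$center_convention)
  g <- expand.grid(x_mm = off, y_mm = off)
  g$r_mm <- sqrt(g$x_mm^2 + g$y_mm^2)
  tol <- 1e-9
  keep <- g$r_mm <= outer / 2 + tol
  if (region$kind == "annulus")
    keep <- keep & g$r_mm > region$inner_diameter_mm / 2 + tol
  g <- g[keep, , drop = FALSE]
  g$ix <- as.integer(round(g$x_mm / grid$in_plane_voxel_mm -
                             if (grid$center_convention == "voxel_corner") 0.5 else 0))
  g$iy <- as.integer(round(g$y_mm / grid$in_plane_voxel_mm -
                             if (grid$center_convention == "voxel_corner") 0.5 else 0))
  rownames(g) <- NULL
  g[, c("ix", "iy", "x_mm", "y_mm", "r_mm")]
}

#' Area-quotient voxel budget of a disc
#'
#' `floor(pi (d/2)^2 / pitch^2)`: the number of whole voxels fitting the disc
#' area. This is the convention under which the 12 mm targeted region holds
#' 46 voxels at 1.56 mm pitch; it deliberately differs from centre-membership
#' counting (see [voxel_centers_in_region()]), and both are exposed.
#'
#' @param grid a [scan_grid()].
#' @param diameter_mm disc diameter in mm.
#' @return integer voxel count.
#' @export
disc_voxel_budget <- function(grid, diameter_mm) {
  stopifnot(inherits(grid, "scan_grid"))
  if (diameter_mm < 0) stop_invalid("diameter must be non-negative")
  as.integer(floor(pi * (diameter_mm / 2)^2 / voxel_area(grid)))
}

#' Translate an ablated-volume ratio into a diameter change
#'
#' Under isotropic scaling a volume ratio `v` corresponds to a relative
#' diameter change `v^(1/3) - 1`. E.g. a +31% volume (ratio 1.31) is a +9.4%
#' diameter change.
#'
#' @param ratio positive volume ratio (treated/reference).
#' @return diameter change in percent.
#' @export
diameter_change_from_volume_ratio <- function(ratio) {
  if (any(ratio <= 0)) stop_invalid("volume ratio must be positive")
  (ratio^(1 / 3) - 1) * 100
}
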