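# PRF-shift thermometry: phase series -> temperature-change series, temporal
# averaging, and the per-phantom absorption-correction normalisation.

#' Thermometry processing configuration
#'
#' @param prf_coeff_ppm_per_C PRF coefficient alpha (ppm/degC), 0.0094.
#' @param temporal_average_factor factor for accuracy averaging (4).
#' @param display_average_factor factor for display/measurement averaging (32).
#' @return an object of class `thermometry_config`.
#' @export
thermometry_config <- function(prf_coeff_ppm_per_C = 0.0094,
                               temporal_average_factor = 4,
                               display_average_factor = 32) {
  if (prf_coeff_ppm_per_C <= 0) stop_invalid("PRF coefficient must be > 0")
  if (temporal_average_factor < 1 || display_average_factor < 1)
    stop_invalid("averaging factors must be >= 1")
  structure(list(prf_coeff_ppm_per_C = prf_coeff_ppm_per_C,
                 temporal_average_factor = as.integer(temporal_average_factor),
                 display_average_factor = as.integer(display_average_factor)),
            class = "thermometry_config")
}

#' Convert a phase series to a temperature-change series
#'
#' `dT = wrap(phase - reference phase) / k`, with `k` from
#' [prf_phase_coefficient()] evaluated at `effective_alpha` (the nominal PRF
#' coefficient, or the absorption-corrected one from [corrected_prf()]).
#' The reference phase is the circular mean over the reference frames: by
#' default all frames acquired during the pre-sonication delay (lower
#' reference noise than a single frame), or frame 1 when the series carries
#' no sonication timing.
#'
#' @param series an `image_series` from [render_images()].
#' @param config a [thermometry_config()].
#' @param reference_frame_index indices of the reference frames; `NULL` for
#'   the default above.
#' @param effective_alpha PRF coefficient actually applied (defaults to
#'   `config$prf_coeff_ppm_per_C`).
#' @return an object of class `thermal_map_series`: `dT` (row, col, frame,
#'   degC), `times`, `valid` (logical, same shape), `grid`, `k_rad_per_C`,
#'   `alpha`, `average_factor`.
#' @export
phase_to_temperature <- function(series, config = thermometry_config(),
                                 reference_frame_index = NULL,
                                 effective_alpha = NULL) {
  stopifnot(inherits(series, "image_series"))
  nf <- dim(series$phase)[3]
  if (is.null(reference_frame_index)) {
    if (!is.null(series$sonication))
      reference_frame_index <- which(series$times < series$sonication$delay_s)
    if (!length(reference_frame_index)) reference_frame_index <- 1L
  }
  if (any(reference_frame_index < 1) || any(reference_frame_index > nf))
    stop_invalid("reference frame index out of range (1..%d)", nf)
  alpha <- effective_alpha %||% config$prf_coeff_ppm_per_C
  k <- prf_phase_coefficient(series$acq, alpha)
  ref <- series$phase[, , reference_frame_index, drop = FALSE]
  phi_ref <- Arg(apply(exp(1i * ref), c(1, 2), mean))
  dT <- array(0, dim(series$phase))
  for (f in seq_len(nf))
    dT[, , f] <- wrap_phase(series$phase[, , f] - phi_ref) / k
  structure(list(dT = dT, times = series$times,
                 valid = array(TRUE, dim(dT)), grid = series$grid,
                 k_rad_per_C = k, alpha = alpha, average_factor = 1L,
                 sonication = series$sonication),
            class = "thermal_map_series")
}

#' @export
print.thermal_map_series <- function(x, ...) {
  cat(sprintf("<thermal_map_series> %d x %d x %d frames, alpha %.4g ppm/degC, x%d averaged\n",
              dim(x$dT)[1], dim(x$dT)[2], dim(x$dT)[3], x$alpha,
              x$average_factor))
  invisible(x)
}

# Non-overlapping block means along the last dimension; trailing frames not
# filling a block are dropped.
block_average <- function(arr, times, factor) {
  nf <- dim(arr)[3]
  nb <- nf %/% factor
  if (nb < 1) stop_invalid("averaging factor %d exceeds series length %d",
                           factor, nf)
  out <- array(0, c(dim(arr)[1:2], nb))
  tout <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * factor + 1):(b * factor)
    a <- arr[, , idx, drop = FALSE]
    out[, , b] <- rowMeans(a, dims = 2)
    tout[b] <- mean(times[idx])
  }
  list(arr = out, times = tout)
}

#' Temporal averaging of a series
#'
#' Non-overlapping block means by `factor`; timestamps become block
#' midpoints; trailing frames not filling a block are dropped. For an
#' `image_series` the complex signal is averaged (magnitude and phase follow
#' from the complex mean). On independent noise the map noise sd shrinks by
#' `sqrt(factor)`.
#'
#' @param x an `image_series` or `thermal_map_series`.
#' @param factor integer averaging factor (1 = identity).
#' @return the same class as `x`.
#' @export
temporal_average <- function(x, factor) {
  if (factor < 1) stop_invalid("averaging factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  if (inherits(x, "image_series")) {
    z <- x$magnitude * exp(1i * x$phase)
    re <- block_average(Re(z), x$times, factor)
    im <- block_average(Im(z), x$times, factor)
    x$magnitude <- sqrt(re$arr^2 + im$arr^2)
    x$phase <- atan2(im$arr, re$arr)
    x$times <- re$times
    x$average_factor <- (x$average_factor %||% 1L) * factor
    x
  } else if (inherits(x, "thermal_map_series")) {
    b <- block_average(x$dT, x$times, factor)
    x$dT <- b$arr
    x$times <- b$times
    x$valid <- array(TRUE, dim(b$arr))
    x$average_factor <- x$average_factor * factor
    x
  } else stop_invalid("temporal_average: unsupported input")
}

# Mean dT over the (2h+1) x (2h+1) ROI around the focal centre at the last
# frame whose timestamp is <= end_s.
roi_mean_at <- function(tms, end_s, half = 1L) {
  f <- max(which(tms$times <= end_s + 1e-9))
  nr <- dim(tms$dT)[1]; nc <- dim(tms$dT)[2]
  r0 <- nr %/% 2L; c0 <- nc %/% 2L
  mean(tms$dT[(r0 - half):(r0 + half), (c0 - half):(c0 + half), f])
}

#' Per-phantom absorption-correction coefficients
#'
#' For each phantom, the temperature rise averaged over a 3 x 3 voxel region
#' at the focal centre at end of sonication, averaged over its reference
#' sonications (performed away from the marker), is divided by the grand
#' mean over all phantoms. The coefficients quantify each gel's relative
#' ultrasound absorption and average to exactly 1 by construction.
#'
#' @param reference_runs list (one element per phantom) of lists of
#'   `thermal_map_series` from the reference sonications.
#' @param sonication_end_s end-of-sonication time (s); defaults to the value
#'   carried by the series.
#' @param roi_half half-width of the ROI (1 = 3 x 3 voxels).
#' @return an object of class `absorption_correction`: `coefficients`
#'   (per phantom), `per_phantom_roi_C`, `grand_mean_C`.
#' @export
absorption_correction <- function(reference_runs, sonication_end_s = NULL,
                                  roi_half = 1L) {
  per <- vapply(reference_runs, function(runs) {
    mean(vapply(runs, function(tms) {
      end_s <- sonication_end_s %||%
        (tms$sonication$delay_s + tms$sonication$duration_s)
      roi_mean_at(tms, end_s, roi_half)
    }, numeric(1)))
  }, numeric(1))
  grand <- mean(per)
  if (abs(grand) < .Machine$double.eps)
    stop_invalid("degenerate input: zero grand-mean temperature rise")
  structure(list(coefficients = per / grand, per_phantom_roi_C = per,
                 grand_mean_C = grand, n_phantoms = length(per)),
            class = "absorption_correction")
}

#' Absorption-corrected PRF coefficient
#'
#' `alpha_eff = alpha * c`: the effective PRF coefficient of a phantom
#' scales with its correction coefficient, so that converting its phase maps
#' with `alpha_eff` deflates the temperature by `c` and makes phantoms of
#' different gel absorption directly comparable (a gel absorbing 5% more
#' heats 5% more, and reports 5% less per radian). Applying the corrected
#' coefficient to a phantom whose heating scales with `c` recovers
#' reference-comparable temperature maps exactly.
#'
#' @param config a [thermometry_config()].
#' @param coefficient the phantom's correction coefficient (dimensionless,
#'   cohort mean 1) from [absorption_correction()].
#' @return effective PRF coefficient in ppm/degC.
#' @export
corrected_prf <- function(config, coefficient) {
  if (coefficient <= 0) stop_invalid("correction coefficient must be > 0")
  config$prf_coeff_ppm_per_C * coefficient
}
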