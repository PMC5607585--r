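# Finite-difference heating simulation. The phantom is an unperfused gel, so
# the bioheat equation reduces to the heat equation with a moving Gaussian
# power-deposition source following the circular sonication trajectory:
#   dT/dt = D lap(T) + a * source(x, t)
# solved explicitly (FTCS) with insulated (Neumann) boundaries.

# -6 dB full width -> Gaussian sigma.
width_to_sigma <- function(width_mm) width_mm / (2 * sqrt(2 * log(2)))

# Dwell table of the sonication trajectory: every dwell point (x, y) with
# its share of the sonication time. Circles are visited uniformly and
# sequentially; each circle's time share is proportional to its
# circumference, split evenly over its points, and the whole pattern is
# swept many times per thermal time constant, so the deposition entering
# the solver is the time average of the pattern (see vignette).
dwell_table <- function(protocol) {
  d <- protocol$circle_diameters_mm
  p <- protocol$points_per_circle
  share <- if (sum(d) > 0) d / sum(d) else rep(1 / length(d), length(d))
  do.call(rbind, lapply(seq_along(d), function(i) {
    ang <- 2 * pi * (seq_len(p) - 1) / p
    data.frame(circle = i, weight = share[i] / p,
               x = (d[i] / 2) * cos(ang), y = (d[i] / 2) * sin(ang))
  }))
}

lap3 <- function(T, h) {
  n1 <- dim(T)[1]; n2 <- dim(T)[2]; n3 <- dim(T)[3]
  p1 <- c(2:n1, n1); m1 <- c(1, 1:(n1 - 1))
  p2 <- c(2:n2, n2); m2 <- c(1, 1:(n2 - 1))
  p3 <- c(2:n3, n3); m3 <- c(1, 1:(n3 - 1))
  (T[p1, , ] + T[m1, , ] + T[, p2, ] + T[, m2, ] +
     T[, , p3] + T[, , m3] - 6 * T) / h^2
}

#' Simulate the heating of one sonication
#'
#' Explicit finite-difference solution of the heat equation on an isotropic
#' grid around the focus. The source is a 3D Gaussian whose -6 dB widths
#' match the transducer's focal spot, swept along the circular trajectory
#' (time-averaged deposition pattern), active during
#' `[delay, delay + duration]`, with peak amplitude
#' `source_scale * acoustic_power * absorption_factor` at a stationary
#' focus.
#'
#' @param protocol a [sonication_protocol()].
#' @param transducer a [transducer_model()] (its `source_scale` sets the
#'   heating amplitude; see [calibrate_source()]).
#' @param phantom a [phantom_spec()].
#' @param grid3d a [sim_grid()].
#' @param time_step_s solver step; must satisfy the FTCS stability bound
#'   `dt <= h^2 / (6 D)`.
#' @param frame_interval_s spacing of recorded temperature frames.
#' @return an object of class `heating_field`: list with `dT`
#'   (4D array x,y,z,frame in degC), `times` (s), `grid`.
#' @export
simulate_heating <- function(protocol, transducer, phantom,
                             grid3d = sim_grid(), time_step_s = 0.05,
                             frame_interval_s = 0.5) {
  stopifnot(inherits(protocol, "sonication_protocol"),
            inherits(transducer, "transducer_model"),
            inherits(phantom, "phantom_spec"),
            inherits(grid3d, "sim_grid"))
  D <- phantom$thermal_diffusivity_mm2_s
  h <- grid3d$spacing_mm
  dt <- time_step_s
  if (D > 0 && dt > h^2 / (6 * D))
    stop_invalid("time step %.3g s violates the stability bound %.3g s",
                 dt, h^2 / (6 * D))
  rmax <- max(protocol$circle_diameters_mm) / 2
  if (rmax > max(grid3d$x))
    stop_invalid("sonication trajectory (radius %.1f mm) outside the grid", rmax)

  sched <- dwell_table(protocol)
  sig <- width_to_sigma(transducer$focal_widths_mm)
  # time-averaged deposition pattern of the swept trajectory
  pattern <- 0
  for (i in seq_len(nrow(sched))) {
    gx <- exp(-(grid3d$x - sched$x[i])^2 / (2 * sig[1]^2))
    gy <- exp(-(grid3d$y - sched$y[i])^2 / (2 * sig[2]^2))
    gz <- exp(-grid3d$z^2 / (2 * sig[3]^2))
    pattern <- pattern + sched$weight[i] * outer(outer(gx, gy), gz)
  }

  amp <- transducer$source_scale * protocol$acoustic_power_W *
    phantom$absorption_factor
  t_on <- protocol$pre_sonication_delay_s
  t_off <- t_on + protocol$duration_s
  total <- protocol_total_time(protocol)
  n_steps <- ceiling(total / dt)
  times <- seq(0, by = frame_interval_s,
               length.out = floor(total / frame_interval_s) + 1L)

  n <- grid3d$n
  T <- array(0, c(n, n, n))
  dT <- array(0, c(n, n, n, length(times)))
  next_frame <- 2L  # frame 1 is t = 0, all zero
  perf <- phantom$perfusion_rate_per_s
  for (s in seq_len(n_steps)) {
    tm <- (s - 0.5) * dt
    dTdt <- if (D > 0) D * lap3(T, h) else 0
    if (amp > 0 && tm >= t_on && tm < t_off)
      dTdt <- dTdt + amp * pattern
    T <- T + dt * dTdt
    if (perf > 0) T <- T - dt * perf * T
    t_now <- s * dt
    while (next_frame <= length(times) && t_now >= times[next_frame] - 1e-9) {
      dT[, , , next_frame] <- T
      next_frame <- next_frame + 1L
    }
  }
  structure(list(dT = dT, times = times, grid = grid3d, protocol = protocol),
            class = "heating_field")
}

#' Scale a heating field by a constant
#'
#' The solution is linear in the source amplitude, so the field of a phantom
#' differing only in absorption (or of a different calibration scale) is an
#' exact rescaling; this avoids re-running the solver.
#'
#' @param field a `heating_field`.
#' @param factor multiplicative factor.
#' @return the rescaled `heating_field`.
#' @export
scale_heating_field <- function(field, factor) {
  stopifnot(inherits(field, "heating_field"))
  field$dT <- field$dT * factor
  field
}

#' Calibrate the source amplitude to a target peak temperature rise
#'
#' Runs one reference simulation at unit `source_scale` and exploits the
#' linearity of the temperature rise in the source amplitude to return the
#' scale that makes the peak rise equal `target_peak_C`. The sonication
#' pattern studied here is calibrated so the coronal thermal map (the 5 mm
#' slab average, which is what MR thermometry observes) peaks at 30 degC;
#' `peak_on = "field"` calibrates the 3D point peak instead.
#'
#' @param target_peak_C target peak temperature rise in degC.
#' @param protocol,transducer,phantom,grid3d,time_step_s,frame_interval_s
#'   as in [simulate_heating()].
#' @param peak_on `"coronal_map"` (default) or `"field"`.
#' @return the calibrated `source_scale` (degC/s/W at a stationary focus).
#' @export
calibrate_source <- function(target_peak_C, protocol, transducer,
                             phantom = phantom_spec(), grid3d = sim_grid(),
                             time_step_s = 0.05, frame_interval_s = 0.5,
                             peak_on = c("coronal_map", "field")) {
  peak_on <- match.arg(peak_on)
  if (target_peak_C < 0) stop_invalid("target peak must be >= 0")
  if (target_peak_C == 0) return(0)
  transducer$source_scale <- 1
  f <- simulate_heating(protocol, transducer, phantom, grid3d,
                        time_step_s, frame_interval_s)
  peak <- if (peak_on == "field") max(f$dT) else max(slab_average(f, "coronal"))
  if (peak <= 0)
    stop_invalid("calibration failed: zero simulated response")
  target_peak_C / peak
}

#' Average a heating field over an imaging slab
#'
#' Restricts the 3D field to the 5 mm imaging slab of a coronal (x, y; slab
#' along z) or sagittal (y, z; slab along x) slice through the focus, by
#' averaging the grid layers whose centres fall within the slab.
#'
#' @param field a `heating_field`.
#' @param orientation `"coronal"` or `"sagittal"`.
#' @param thickness_mm slab thickness in mm.
#' @return 3D array (in-plane row, in-plane col, frame).
#' @export
slab_average <- function(field, orientation = c("coronal", "sagittal"),
                         thickness_mm = 5) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(field, "heating_field"))
  g <- field$grid
  take <- function(k) {
    a <- if (orientation == "coronal") field$dT[, , k, , drop = FALSE]
         else field$dT[k, , , , drop = FALSE]
    dm <- dim(a)
    dim(a) <- if (orientation == "coronal") dm[c(1, 2, 4)] else dm[c(2, 3, 4)]
    a
  }
  keep <- if (orientation == "coronal") which(abs(g$z) <= thickness_mm / 2)
          else which(abs(g$x) <= thickness_mm / 2)
  if (!length(keep)) stop_invalid("slab contains no grid layer")
  out <- take(keep[1])
  for (k in keep[-1]) out <- out + take(k)
  out / length(keep)
}
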