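# Synthetic contracting-ventricle phantom.
#
# The phantom is a 2-D incompressible annulus. Each angular sector s has a
# contraction fraction c_s and an activation delay delta_s. The endocardial
# radius follows
#     R_endo(t) = r_endo0 * (1 - c_s * w(t - delta_s)),
#     w(u) = sin^2(pi * (u mod T) / T),
# and area preservation maps a material point at ED radius R to
#     r(R, t) = sqrt(R^2 + R_endo(t)^2 - r_endo0^2),
# so the radial engineering strain at material radius R is exactly
#     eps_r(R, t) = R / r(R, t) - 1
# (positive: the wall thickens as the cavity shrinks). The Eulerian radial
# velocity field reduces to v(rho, t) = R_endo * dR_endo/dt / rho for
# rho >= R_endo(t); inside the cavity a linear ramp v = (dR_endo/dt) * rho /
# R_endo keeps the field continuous and bounded. Sector parameters are
# blended linearly across sector boundaries over a configurable angular
# half-width so the field stays differentiable.

#' Specify a contracting-annulus phantom
#'
#' @param grid_size pixels per side of the square image grid.
#' @param pixel_spacing_mm isotropic pixel spacing, mm.
#' @param n_frames frames per cardiac cycle (frame 0 = end-diastole); the
#'   cycle length is `n_frames * frame_duration_ms`.
#' @param frame_duration_ms frame duration, ms.
#' @param r_endo0_mm,r_epi0_mm end-diastolic endocardial/epicardial radii, mm.
#' @param contraction_fraction per-sector dimensionless contraction `c_s` in
#'   `[0, 1)` (endocardial radius at peak contraction is
#'   `(1 - c_s) * r_endo0_mm`); recycled to `n_sectors`.
#' @param activation_delay_ms per-sector activation delay, ms, in
#'   `[0, cycle)`; recycled to `n_sectors`.
#' @param n_sectors number of angular sectors over which amplitudes and
#'   delays are prescribed (default matches the slice level: 6 for
#'   basal/mid, 4 for apical).
#' @param noise_sd_mm_s standard deviation of additive Gaussian velocity
#'   noise, mm/s.
#' @param seed RNG seed for the noise (`NULL` = use the current stream).
#' @param slice_level `"apical"`, `"mid"`, or `"basal"`.
#' @param blend_deg angular half-width (degrees) of the linear blending of
#'   sector parameters across sector boundaries.
#' @param anterior_reference_angle_rad angle of the first sector boundary
#'   (counterclockwise from image right; default straight up).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 128L,
                         pixel_spacing_mm = 0.5,
                         n_frames = 40L,
                         frame_duration_ms = 25,
                         r_endo0_mm = 20,
                         r_epi0_mm = 28,
                         contraction_fraction = 0.25,
                         activation_delay_ms = 0,
                         n_sectors = NULL,
                         noise_sd_mm_s = 0,
                         seed = NULL,
                         slice_level = c("mid", "basal", "apical"),
                         blend_deg = 5,
                         anterior_reference_angle_rad = pi / 2) {
  slice_level <- match.arg(slice_level)
  if (is.null(n_sectors)) n_sectors <- .n_sectors_for_level(slice_level)
  spec <- structure(list(
    grid_size = as.integer(grid_size),
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    n_frames = as.integer(n_frames),
    frame_duration_ms = as.numeric(frame_duration_ms),
    r_endo0_mm = as.numeric(r_endo0_mm),
    r_epi0_mm = as.numeric(r_epi0_mm),
    contraction_fraction = rep_len(as.numeric(contraction_fraction), n_sectors),
    activation_delay_ms = rep_len(as.numeric(activation_delay_ms), n_sectors),
    n_sectors = as.integer(n_sectors),
    noise_sd_mm_s = as.numeric(noise_sd_mm_s),
    seed = seed,
    slice_level = slice_level,
    blend_deg = as.numeric(blend_deg),
    anterior_reference_angle_rad = .wrap_angle(anterior_reference_angle_rad)
  ), class = "phantom_spec")
  .validate_phantom_spec(spec)
  spec
}

.validate_phantom_spec <- function(spec) {
  cyc <- spec$n_frames * spec$frame_duration_ms
  if (!(spec$r_epi0_mm > spec$r_endo0_mm && spec$r_endo0_mm > 0))
    .stopf("need r_epi0_mm > r_endo0_mm > 0 (got %g, %g)",
           spec$r_epi0_mm, spec$r_endo0_mm)
  if (any(spec$contraction_fraction < 0 | spec$contraction_fraction >= 1))
    .stopf("contraction_fraction must lie in [0, 1)")
  if (any(spec$activation_delay_ms < 0 | spec$activation_delay_ms >= cyc))
    .stopf("activation_delay_ms must lie in [0, cycle = %g ms)", cyc)
  if (spec$n_frames < 10L)
    .stopf("n_frames = %d; at least 10 frames are required", spec$n_frames)
  wall_px <- (spec$r_epi0_mm - spec$r_endo0_mm) / spec$pixel_spacing_mm
  if (wall_px < 2)
    .stopf("wall thickness %g mm spans %.2f px (< 2 px) at %g mm spacing",
           spec$r_epi0_mm - spec$r_endo0_mm, wall_px, spec$pixel_spacing_mm)
  half_extent <- (spec$grid_size - 1) / 2 * spec$pixel_spacing_mm
  if (spec$r_epi0_mm > half_extent)
    .stopf("epicardial radius %g mm exceeds the grid half-extent %g mm",
           spec$r_epi0_mm, half_extent)
  invisible(spec)
}

# Blend per-sector values across boundaries: piecewise constant in the
# sector interior, linear over +/- beta at each boundary. `theta` in radians.
.sector_blend <- function(theta, values, ref, beta) {
  m <- length(values)
  width <- 2 * pi / m
  u <- .wrap_angle(theta - ref)
  idx <- pmin(floor(u / width), m - 1)          # 0-based sector
  d <- u - idx * width                          # position within sector
  out <- values[idx + 1]
  if (beta > 0) {
    prev <- values[(idx - 1) %% m + 1]
    nxt <- values[(idx + 1) %% m + 1]
    lo <- d < beta                              # near the leading boundary
    out[lo] <- out[lo] + (0.5 - d[lo] / (2 * beta)) * (prev[lo] - out[lo])
    hi <- d > width - beta                      # near the trailing boundary
    out[hi] <- out[hi] +
      (0.5 - (width - d[hi]) / (2 * beta)) * (nxt[hi] - out[hi])
  }
  out
}

# the activation waveform and its time derivative (arguments in ms)
.waveform <- function(u, cycle_ms) sin(pi * ((u %% cycle_ms) / cycle_ms))^2
.waveform_dt <- function(u, cycle_ms)
  (pi / cycle_ms) * sin(2 * pi * ((u %% cycle_ms) / cycle_ms))  # per ms

#' Generate a phantom velocity cine with analytic strain truth
#'
#' Produces the Eulerian velocity field of the incompressible contracting
#' annulus described in [phantom_spec()], sampled at pixel centers for every
#' frame, plus the closed-form per-sector truth: the mid-wall radial strain
#' curve, the true time-to-peak `TTP_s = (T/2 + delta_s) mod T`, and the peak
#' strain. Sectors with `c_s = 0` do not contract; their truth TTP is `NA`.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `cine` (a [velocity_cine()]) and `truth`
#'   (class `strain_truth`: matrix `curve` of sector x frame mid-wall strain,
#'   vectors `ttp_ms` and `peak`, and the evaluation radius
#'   `mid_wall_radius_mm`).
#' @export
generate_phantom <- function(spec) {
  .validate_phantom_spec(spec)
  n <- spec$grid_size
  h <- spec$pixel_spacing_mm
  nf <- spec$n_frames
  cyc <- nf * spec$frame_duration_ms
  c0 <- (n - 1) / 2
  col <- matrix(rep(0:(n - 1), each = n), n)
  row <- matrix(rep(0:(n - 1), times = n), n)
  x <- (col - c0) * h
  y <- (c0 - row) * h
  rho <- sqrt(x^2 + y^2)
  theta <- .wrap_angle(atan2(y, x))
  mask <- rho >= spec$r_endo0_mm & rho <= spec$r_epi0_mm

  beta <- spec$blend_deg * pi / 180
  c_px <- .sector_blend(theta, spec$contraction_fraction,
                        spec$anterior_reference_angle_rad, beta)
  d_px <- .sector_blend(theta, spec$activation_delay_ms,
                        spec$anterior_reference_angle_rad, beta)

  vel <- array(0, dim = c(nf, n, n, 2L))
  rho_safe <- pmax(rho, 1e-9)
  ux <- x / rho_safe
  uy <- y / rho_safe
  for (k in seq_len(nf)) {
    t <- (k - 1) * spec$frame_duration_ms
    u <- t - d_px
    Re <- spec$r_endo0_mm * (1 - c_px * .waveform(u, cyc))
    Rp <- -spec$r_endo0_mm * c_px * .waveform_dt(u, cyc) * 1000  # mm/s
    v <- ifelse(rho >= Re, Re * Rp / rho_safe, Rp * rho / pmax(Re, 1e-9))
    vel[k, , , 1] <- -v * uy   # +row is "down": v_row = -v_y
    vel[k, , , 2] <- v * ux
  }
  if (spec$noise_sd_mm_s > 0) {
    vel <- vel + .with_seed(spec$seed,
      array(stats::rnorm(length(vel), sd = spec$noise_sd_mm_s), dim = dim(vel)))
  }

  cine <- velocity_cine(vel, mask, rep(h, 2), spec$frame_duration_ms,
                        spec$slice_level)
  list(cine = cine, truth = .phantom_truth(spec))
}

# closed-form mid-wall truth per sector
.phantom_truth <- function(spec) {
  cyc <- spec$n_frames * spec$frame_duration_ms
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_duration_ms
  Rm <- (spec$r_endo0_mm + spec$r_epi0_mm) / 2
  m <- spec$n_sectors
  curve <- matrix(0, m, spec$n_frames)
  for (s in seq_len(m)) {
    Re <- spec$r_endo0_mm *
      (1 - spec$contraction_fraction[s] *
         .waveform(times - spec$activation_delay_ms[s], cyc))
    r <- sqrt(Rm^2 + Re^2 - spec$r_endo0_mm^2)
    curve[s, ] <- Rm / r - 1
  }
  ttp <- ifelse(spec$contraction_fraction > 0,
                (cyc / 2 + spec$activation_delay_ms) %% cyc, NA_real_)
  Re_pk <- spec$r_endo0_mm * (1 - spec$contraction_fraction)
  peak <- Rm / sqrt(Rm^2 + Re_pk^2 - spec$r_endo0_mm^2) - 1
  structure(list(curve = curve, ttp_ms = ttp, peak = peak,
                 times_ms = times, mid_wall_radius_mm = Rm),
            class = "strain_truth")
}

#' @export
as.data.frame.strain_truth <- function(x, ...) {
  m <- nrow(x$curve); nf <- ncol(x$curve)
  data.frame(sector = rep(seq_len(m), each = nf),
             frame = rep(seq_len(nf) - 1L, times = m),
             time_ms = rep(x$times_ms, times = m),
             strain = as.vector(t(x$curve)))
}

#' @export
print.strain_truth <- function(x, ...) {
  cat(sprintf("strain_truth: %d sectors x %d frames, mid-wall R = %g mm\n",
              nrow(x$curve), ncol(x$curve), x$mid_wall_radius_mm))
  cat("  peak strain:", paste(sprintf("%.3f", x$peak), collapse = " "), "\n")
  cat("  TTP (ms):   ", paste(format(x$ttp_ms), collapse = " "), "\n")
  invisible(x)
}
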