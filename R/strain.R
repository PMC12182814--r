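# Velocity-to-strain engine: material-point tracking, least-squares
# deformation gradients, AHA segmentation, and segmental strain/strain-rate
# time curves.

#' Track myocardial material points through the cardiac cycle
#'
#' Every ED-mask pixel is integrated forward with the explicit Euler scheme
#' `x(k+1) = x(k) + v(x(k), k) * dt`, sampling the velocity field with
#' bilinear interpolation. Where the cine's velocity is undefined
#' (non-finite) it is extrapolated from the nearest defined pixels before
#' interpolation. Positions are reported in mm in a centroid-origin frame
#' (x = image right, y = image up). Trajectories that leave the image bounds
#' are flagged and excluded from downstream segment averages.
#'
#' @param cine a [velocity_cine()].
#' @param geometry a [slice_geometry()]; default: mask centroid, anterior
#'   reference up.
#' @return an object of class `lv_trajectories`: `pos` (`n_px x 2 x
#'   n_frames` array of (x, y) mm), `rc` (0-based ED pixel coordinates),
#'   `flagged` (logical; left the image), plus grid metadata.
#' @export
track_displacements <- function(cine, geometry = default_geometry(cine)) {
  validate_cine(cine)
  nf <- dim(cine$velocity)[1]
  nr <- dim(cine$velocity)[2]
  nc <- dim(cine$velocity)[3]
  sp <- cine$pixel_spacing_mm
  dt_s <- cine$frame_duration_ms / 1000
  centroid <- geometry$centroid

  rc <- which(cine$ed_mask, arr.ind = TRUE) - 1L
  colnames(rc) <- c("row", "col")
  xy0 <- .px_to_mm(rc, centroid, sp)
  n_px <- nrow(rc)

  pos <- array(NA_real_, c(n_px, 2L, nf))
  pos[, , 1] <- xy0
  flagged <- rep(FALSE, n_px)

  for (k in seq_len(nf - 1)) {
    vrow <- cine$velocity[k, , , 1]
    vcol <- cine$velocity[k, , , 2]
    if (any(!is.finite(vrow))) vrow <- .nn_fill(vrow)
    if (any(!is.finite(vcol))) vcol <- .nn_fill(vcol)
    p <- .mm_to_px(pos[, , k], centroid, sp)
    out <- p[, 1] < 0 | p[, 1] > nr - 1 | p[, 2] < 0 | p[, 2] > nc - 1
    flagged <- flagged | out
    vr <- .bilinear(vrow, p[, 1], p[, 2])
    vc <- .bilinear(vcol, p[, 1], p[, 2])
    # convert pixel-axis velocity (mm/s) to the display frame: x = +col, y = -row
    pos[, 1, k + 1] <- pos[, 1, k] + vc * dt_s
    pos[, 2, k + 1] <- pos[, 2, k] - vr * dt_s
  }
  if (any(flagged))
    message(sum(flagged), " trajectories left the image bounds and were flagged")

  structure(list(pos = pos, rc = rc, flagged = flagged,
                 grid_dim = c(nr, nc), pixel_spacing_mm = sp,
                 frame_duration_ms = cine$frame_duration_ms,
                 slice_level = cine$slice_level, centroid = centroid),
            class = "lv_trajectories")
}

#' Per-pixel radial and circumferential strain from tracked trajectories
#'
#' For each ED-mask pixel the local deformation gradient `F(k)` is estimated
#' by least squares over its ED neighborhood (all mask pixels within a
#' 2-pixel radius): the current relative positions of the neighbors are
#' regressed on their ED relative positions. With `C = F'F`, the stretch
#' along an ED unit direction `e` is `sqrt(e'Ce)`, and the engineering
#' strains are `eps_r = sqrt(e_r'Ce_r) - 1` and `eps_c = sqrt(e_c'Ce_c) - 1`
#' for the ED radial and tangential directions about the centroid. Pixels
#' with fewer than 3 valid neighbors, a numerically singular (collinear)
#' neighborhood, or a flagged trajectory are excluded.
#'
#' @param traj an `lv_trajectories` object from [track_displacements()].
#' @param geometry a [slice_geometry()]; its centroid defines the radial
#'   direction field (defaults to the centroid used for tracking).
#' @return an object of class `lv_strain_maps`: matrices `radial` and
#'   `circumferential` (`n_px x n_frames`, dimensionless strain), `valid`
#'   (logical per pixel), plus the pixel bookkeeping from `traj`.
#' @export
compute_strain <- function(traj, geometry = NULL) {
  pos <- traj$pos
  n_px <- dim(pos)[1]
  nf <- dim(pos)[3]
  centroid <- if (is.null(geometry)) traj$centroid else geometry$centroid
  xy0 <- .px_to_mm(traj$rc, centroid, traj$pixel_spacing_mm)
  R0 <- sqrt(rowSums(xy0^2))
  if (any(R0 < 1e-9)) .stopf("mask pixel coincides with the centroid")
  er <- xy0 / R0
  ec <- cbind(-er[, 2], er[, 1])   # tangential, counterclockwise

  # neighbor lists over the ED grid (radius-2 disc, excluding self)
  nr <- traj$grid_dim[1]
  index_of <- matrix(NA_integer_, nr, traj$grid_dim[2])
  index_of[traj$rc + 1L] <- seq_len(n_px)
  offs <- as.matrix(expand.grid(dr = -2:2, dc = -2:2))
  offs <- offs[rowSums(offs^2) <= 4 & rowSums(abs(offs)) > 0, ]

  radial <- matrix(NA_real_, n_px, nf)
  circum <- matrix(NA_real_, n_px, nf)
  valid <- !traj$flagged
  n_singular <- 0L
  for (i in seq_len(n_px)) {
    if (!valid[i]) next
    rr <- traj$rc[i, 1] + offs[, 1] + 1L
    cc <- traj$rc[i, 2] + offs[, 2] + 1L
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(index_of)
    js <- index_of[cbind(rr[ok], cc[ok])]
    js <- js[!is.na(js)]
    js <- js[!traj$flagged[js]]
    if (length(js) < 3L) { valid[i] <- FALSE; next }
    A <- xy0[js, , drop = FALSE] -
      matrix(xy0[i, ], length(js), 2, byrow = TRUE)
    G <- crossprod(A)
    if (rcond(G) < 1e-10) { valid[i] <- FALSE; n_singular <- n_singular + 1L; next }
    P <- solve(G, t(A))                     # 2 x n
    Bx <- pos[js, 1, ] - matrix(pos[i, 1, ], length(js), nf, byrow = TRUE)
    By <- pos[js, 2, ] - matrix(pos[i, 2, ], length(js), nf, byrow = TRUE)
    FtX <- P %*% Bx                         # rows: d(x')/d(x0), d(x')/d(y0)
    FtY <- P %*% By
    # C = F'F with F' rows = (FtX, FtY) columns; assemble quadratic forms
    c11 <- FtX[1, ]^2 + FtY[1, ]^2
    c22 <- FtX[2, ]^2 + FtY[2, ]^2
    c12 <- FtX[1, ] * FtX[2, ] + FtY[1, ] * FtY[2, ]
    e1 <- er[i, 1]; e2 <- er[i, 2]
    radial[i, ] <- sqrt(pmax(c11 * e1^2 + 2 * c12 * e1 * e2 + c22 * e2^2, 0)) - 1
    f1 <- ec[i, 1]; f2 <- ec[i, 2]
    circum[i, ] <- sqrt(pmax(c11 * f1^2 + 2 * c12 * f1 * f2 + c22 * f2^2, 0)) - 1
  }
  if (n_singular > 0L)
    message(n_singular, " pixels had singular neighborhoods and were excluded")

  structure(list(radial = radial, circumferential = circum, valid = valid,
                 rc = traj$rc, grid_dim = traj$grid_dim,
                 pixel_spacing_mm = traj$pixel_spacing_mm,
                 frame_duration_ms = traj$frame_duration_ms,
                 slice_level = traj$slice_level, centroid = centroid),
            class = "lv_strain_maps")
}

#' Assign every ED-mask pixel to an AHA segment
#'
#' Angular sectors about the centroid: 6 equal 60-degree sectors for basal
#' and mid slices, 4 equal 90-degree sectors for apical slices. The first
#' sector boundary lies at the anterior reference angle and sectors are
#' swept counterclockwise in the display frame, so with the reference
#' pointing "up" and the septum at image left the order is the AHA order
#' returned by [aha_segments()]. The apex cap (segment 17) is never emitted.
#'
#' @param cine a [velocity_cine()].
#' @param geometry a [slice_geometry()].
#' @return an object of class `lv_segment_map`: integer `segment` per mask
#'   pixel (1-based sector index), `labels` (AHA names), `rc`.
#' @export
build_segment_map <- function(cine, geometry = default_geometry(cine)) {
  rc <- which(cine$ed_mask, arr.ind = TRUE) - 1L
  xy <- .px_to_mm(rc, geometry$centroid, cine$pixel_spacing_mm)
  if (any(rowSums(xy^2) < 1e-12))
    .stopf("mask pixel lies exactly at the centroid")
  labels <- aha_segments(geometry$slice_level)
  m <- length(labels)
  width <- 2 * pi / m
  u <- .wrap_angle(atan2(xy[, 2], xy[, 1]) -
                     geometry$anterior_reference_angle_rad)
  seg <- pmin(floor(u / width), m - 1) + 1L
  structure(list(segment = as.integer(seg), labels = labels, rc = rc,
                 slice_level = geometry$slice_level),
            class = "lv_segment_map")
}

#' Segmental strain and strain-rate time curves
#'
#' Per-segment strain at each frame is the mean over the segment's valid
#' pixels; the baseline (frame 0) value is subtracted so every curve starts
#' at 0. Strain rate (1/s) is the centered finite difference of the
#' segmental strain curve, one-sided at the first and last frame.
#'
#' @param maps an `lv_strain_maps` object from [compute_strain()].
#' @param segmap an `lv_segment_map` from [build_segment_map()] (aligned
#'   with the same cine).
#' @param channel `"radial"` (default; used by all downstream dyssynchrony
#'   statistics) or `"circumferential"`.
#' @return an object of class `segment_curves`: `strain` and `strain_rate`
#'   (segment x frame matrices), `times_ms`, `labels`, `n_px` per segment.
#' @export
segment_curves <- function(maps, segmap,
                           channel = c("radial", "circumferential")) {
  channel <- match.arg(channel)
  if (!identical(dim(maps$rc), dim(segmap$rc)) || !all(maps$rc == segmap$rc))
    .stopf("strain maps and segment map are not aligned on the same mask")
  vals <- maps[[channel]]
  nf <- ncol(vals)
  m <- length(segmap$labels)
  strain <- matrix(NA_real_, m, nf,
                   dimnames = list(segmap$labels, NULL))
  n_px <- integer(m)
  for (s in seq_len(m)) {
    sel <- segmap$segment == s & maps$valid
    n_px[s] <- sum(sel)
    if (n_px[s] == 0L)
      .stopf("segment '%s' has no valid pixels", segmap$labels[s])
    strain[s, ] <- colMeans(vals[sel, , drop = FALSE])
  }
  strain <- strain - strain[, 1]
  dt_s <- maps$frame_duration_ms / 1000
  rate <- t(apply(strain, 1, .centered_diff, dt = dt_s))
  structure(list(strain = strain, strain_rate = rate,
                 times_ms = (seq_len(nf) - 1) * maps$frame_duration_ms,
                 frame_duration_ms = maps$frame_duration_ms,
                 labels = segmap$labels, n_px = n_px,
                 slice_level = segmap$slice_level, channel = channel),
            class = "segment_curves")
}

# centered difference, one-sided at the ends; dt in seconds
.centered_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' @export
as.data.frame.segment_curves <- function(x, ...) {
  m <- nrow(x$strain); nf <- ncol(x$strain)
  data.frame(slice = x$slice_level,
             segment = rep(x$labels, each = nf),
             frame = rep(seq_len(nf) - 1L, times = m),
             time_ms = rep(x$times_ms, times = m),
             strain = as.vector(t(x$strain)),
             strain_rate = as.vector(t(x$strain_rate)))
}

#' @export
print.segment_curves <- function(x, ...) {
  cat(sprintf("segment_curves (%s, %s): %d segments x %d frames\n",
              x$slice_level, x$channel, nrow(x$strain), ncol(x$strain)))
  invisible(x)
}

#' Peak strain, time-to-peak, and global radial strain for one slice
#'
#' `peak_RS_pct` is 100 times the maximum of each segmental strain curve;
#' `TTP_ms` is the time of that maximum (earliest frame on ties; `NA` for a
#' flat curve). The slice's global radial strain is, by default, 100 times
#' the peak of the pixel-count-weighted mean segmental strain curve;
#' `global = "mean_of_peaks"` instead averages the segmental peaks.
#'
#' @param curves a [segment_curves()] object.
#' @param global `"peak_of_mean"` (default) or `"mean_of_peaks"`.
#' @return a list of class `strain_summary`: data frame `segments`
#'   (segment, peak_RS_pct, TTP_ms) and scalar `global_RS_pct`.
#' @export
strain_summary <- function(curves, global = c("peak_of_mean", "mean_of_peaks")) {
  global <- match.arg(global)
  peaks <- apply(curves$strain, 1, max)
  ttp <- time_to_peak(curves)
  gcurve <- colSums(curves$strain * curves$n_px) / sum(curves$n_px)
  g <- if (global == "peak_of_mean") max(gcurve) else mean(peaks)
  structure(list(
    segments = data.frame(slice = curves$slice_level,
                          segment = curves$labels,
                          peak_RS_pct = 100 * peaks,
                          TTP_ms = ttp),
    global_RS_pct = 100 * g,
    global_rule = global
  ), class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  print(x$segments, row.names = FALSE)
  cat(sprintf("global RS: %.1f %% (%s)\n", x$global_RS_pct, x$global_rule))
  invisible(x)
}

#' One-call slice analysis: curves, summary, dyssynchrony
#'
#' Convenience wrapper chaining [track_displacements()], [compute_strain()],
#' [build_segment_map()], [segment_curves()], [strain_summary()], and
#' [slice_metrics()].
#'
#' @param cine a [velocity_cine()].
#' @param geometry a [slice_geometry()].
#' @inheritParams strain_summary
#' @inheritParams srcc
#' @inheritParams rure
#' @return list with `curves`, `summary`, `dyssynchrony`.
#' @export
analyze_cine <- function(cine, geometry = default_geometry(cine),
                         global = "peak_of_mean", srcc_agg = "mean",
                         rure_variant = "summed") {
  traj <- track_displacements(cine, geometry)
  maps <- compute_strain(traj, geometry)
  segmap <- build_segment_map(cine, geometry)
  curves <- segment_curves(maps, segmap)
  list(curves = curves,
       summary = strain_summary(curves, global),
       dyssynchrony = slice_metrics(curves, srcc_agg = srcc_agg,
                                    rure_variant = rure_variant))
}
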