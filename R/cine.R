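# Velocity cine container, slice geometry, and the on-disk bundle format.

#' Construct a velocity cine
#'
#' A velocity cine holds per-frame, per-pixel 2-component myocardial
#' velocities for one short-axis slice, together with the end-diastolic (ED)
#' myocardial mask and acquisition metadata. Frame 0 is end-diastole and is
#' the reference configuration for all strain computations; the cardiac cycle
#' length is `n_frames * frame_duration_ms`.
#'
#' Velocity components are stored in pixel-axis order: component 1 is the
#' velocity along the +row direction, component 2 along the +col direction,
#' both in mm/s.
#'
#' @param velocity numeric array `[n_frames, n_row, n_col, 2]`, mm/s.
#' @param ed_mask logical matrix `[n_row, n_col]`; the ED myocardial annulus.
#' @param pixel_spacing_mm length-2 numeric, (row, col) spacing in mm.
#' @param frame_duration_ms frame duration in ms.
#' @param slice_level `"apical"`, `"mid"`, or `"basal"`.
#' @param validate check invariants (finite velocities, annular mask)?
#' @return an object of class `velocity_cine`.
#' @export
velocity_cine <- function(velocity, ed_mask, pixel_spacing_mm,
                          frame_duration_ms,
                          slice_level = c("mid", "basal", "apical"),
                          validate = TRUE) {
  slice_level <- match.arg(slice_level)
  if (length(dim(velocity)) != 4L || dim(velocity)[4] != 2L)
    .stopf("velocity must be a 4-D array [frames, rows, cols, 2]")
  if (!identical(dim(velocity)[2:3], dim(ed_mask)))
    .stopf("ed_mask dimensions %s do not match velocity grid %s",
           paste(dim(ed_mask), collapse = "x"),
           paste(dim(velocity)[2:3], collapse = "x"))
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  obj <- structure(list(
    velocity = velocity,
    ed_mask = ed_mask,
    pixel_spacing_mm = pixel_spacing_mm,
    frame_duration_ms = as.numeric(frame_duration_ms),
    slice_level = slice_level
  ), class = "velocity_cine")
  if (validate) validate_cine(obj)
  obj
}

#' @export
print.velocity_cine <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf(
    "velocity_cine: %d frames x %dx%d px (%.3g x %.3g mm), dt = %g ms, %s slice, %d mask px\n",
    d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
    x$frame_duration_ms, x$slice_level, sum(x$ed_mask)))
  invisible(x)
}

#' Validate a velocity cine
#'
#' Checks that all velocities are finite, that there are at least 10 frames,
#' and that the ED mask is a single 4-connected ring enclosing exactly one
#' hole (the LV cavity).
#'
#' @param cine a [velocity_cine()].
#' @return the cine, invisibly; errors describe the violated invariant.
#' @export
validate_cine <- function(cine) {
  if (!all(is.finite(cine$velocity)))
    .stopf("velocity field contains non-finite values")
  if (dim(cine$velocity)[1] < 10L)
    .stopf("cine has %d frames; at least 10 are required", dim(cine$velocity)[1])
  m <- cine$ed_mask
  if (!any(m)) .stopf("ED mask is empty")
  if (.n_components(m) != 1L)
    .stopf("ED mask is not 4-connected (multiple components)")
  # complement must split into outside + exactly one hole
  ncomp_bg <- .n_components(!m)
  if (ncomp_bg != 2L)
    .stopf("ED mask must enclose exactly one cavity (found %d background regions)",
           ncomp_bg - 1L)
  invisible(cine)
}

# count 4-connected components of a logical matrix (iterative dilation fill)
.n_components <- function(m) {
  remaining <- m
  n <- 0L
  while (any(remaining)) {
    n <- n + 1L
    seed <- which(remaining)[1]
    comp <- matrix(FALSE, nrow(m), ncol(m))
    comp[seed] <- TRUE
    repeat {
      grown <- comp
      grown[-1, ] <- grown[-1, ] | comp[-nrow(m), ]
      grown[-nrow(m), ] <- grown[-nrow(m), ] | comp[-1, ]
      grown[, -1] <- grown[, -1] | comp[, -ncol(m)]
      grown[, -ncol(m)] <- grown[, -ncol(m)] | comp[, -1]
      grown <- grown & remaining
      if (identical(grown, comp)) break
      comp <- grown
    }
    remaining <- remaining & !comp
  }
  n
}

#' Slice geometry: cavity centroid and anterior reference direction
#'
#' The centroid (0-based row, col pixel coordinates) anchors the radial
#' coordinate system; the anterior reference angle points from the centroid
#' toward the anterior RV insertion and fixes the first AHA sector boundary.
#' Angles are measured counterclockwise from the +x (image right) axis in
#' the display frame (y up).
#'
#' @param centroid length-2 numeric, 0-based (row, col).
#' @param anterior_reference_angle_rad angle in `[0, 2*pi)`.
#' @param slice_level `"apical"`, `"mid"`, or `"basal"`.
#' @return an object of class `slice_geometry`.
#' @export
slice_geometry <- function(centroid, anterior_reference_angle_rad = pi / 2,
                           slice_level = c("mid", "basal", "apical")) {
  slice_level <- match.arg(slice_level)
  structure(list(
    centroid = as.numeric(centroid),
    anterior_reference_angle_rad = .wrap_angle(anterior_reference_angle_rad),
    slice_level = slice_level
  ), class = "slice_geometry")
}

#' Default geometry for a cine: mask centroid, anterior reference straight up
#'
#' @param cine a [velocity_cine()].
#' @param anterior_reference_angle_rad reference direction (default `pi/2`,
#'   i.e. image "up", matching the phantom's sector convention).
#' @return a [slice_geometry()].
#' @export
default_geometry <- function(cine, anterior_reference_angle_rad = pi / 2) {
  rc <- which(cine$ed_mask, arr.ind = TRUE) - 1L
  slice_geometry(colMeans(rc), anterior_reference_angle_rad, cine$slice_level)
}

#' Write a velocity cine bundle to a directory
#'
#' The bundle layout is `velocity.nii.gz` (4-D, frame x row x col x
#' component, mm/s), `mask.nii.gz` (ED annulus, 0/1), `meta.json` (spacing,
#' frame duration, slice level, and any extra metadata), and optionally
#' `truth.csv` when the cine comes from the phantom generator.
#'
#' @param cine a [velocity_cine()].
#' @param dir output directory (created if needed).
#' @param truth optional `strain_truth` object to store alongside.
#' @param extra_meta named list merged into `meta.json`.
#' @return `dir`, invisibly.
#' @export
write_cine_bundle <- function(cine, dir, truth = NULL, extra_meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(cine$velocity, file.path(dir, "velocity.nii.gz"))
  RNifti::writeNifti(array(as.integer(cine$ed_mask), dim = dim(cine$ed_mask)),
                     file.path(dir, "mask.nii.gz"))
  meta <- c(list(
    pixel_spacing_mm = cine$pixel_spacing_mm,
    frame_duration_ms = cine$frame_duration_ms,
    slice_level = cine$slice_level,
    n_frames = dim(cine$velocity)[1],
    velocity_components = c("row", "col"),
    velocity_units = "mm/s"
  ), extra_meta)
  if (!is.null(truth)) {
    meta$truth <- list(ttp_ms = truth$ttp_ms, peak_strain = truth$peak,
                       mid_wall_radius_mm = truth$mid_wall_radius_mm)
    utils::write.csv(as.data.frame(truth), file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a velocity cine bundle written by [write_cine_bundle()]
#'
#' @param dir bundle directory.
#' @return list with elements `cine` (a [velocity_cine()]), `truth`
#'   (data frame, or `NULL`), and `meta` (the parsed `meta.json`).
#' @export
read_cine_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  vel <- array(as.numeric(RNifti::readNifti(file.path(dir, "velocity.nii.gz"))),
               dim = dim(RNifti::readNifti(file.path(dir, "velocity.nii.gz"))))
  mask <- as.array(RNifti::readNifti(file.path(dir, "mask.nii.gz"))) > 0
  cine <- velocity_cine(vel, matrix(mask, nrow = dim(vel)[2]),
                        meta$pixel_spacing_mm, meta$frame_duration_ms,
                        meta$slice_level)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  list(cine = cine, truth = truth, meta = meta)
}
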