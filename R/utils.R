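# Internal geometry and numerics helpers shared across the package.
#
# Image convention: pixels are indexed (row, col), 0-based in user-facing
# metadata. Physical coordinates are x = +col direction, y = -row direction
# (so that y points "up" in the usual display with row 0 at the top), both in
# mm. Angles are measured counterclockwise from the +x axis in this frame.

# mm coordinates of pixel centers relative to a centroid given in 0-based
# (row, col) pixel units. `rc` is an n x 2 matrix of 0-based (row, col).
.px_to_mm <- function(rc, centroid, spacing) {
  cbind(x = (rc[, 2] - centroid[2]) * spacing[2],
        y = (centroid[1] - rc[, 1]) * spacing[1])
}

# inverse of .px_to_mm: mm coords -> fractional 0-based (row, col)
.mm_to_px <- function(xy, centroid, spacing) {
  cbind(row = centroid[1] - xy[, 2] / spacing[1],
        col = centroid[2] + xy[, 1] / spacing[2])
}

# angle in [0, 2*pi)
.wrap_angle <- function(a) a %% (2 * pi)

# Bilinear interpolation of matrix M at fractional 0-based (row, col)
# positions, clamped to the image bounds.
.bilinear <- function(M, row, col) {
  nr <- nrow(M); nc <- ncol(M)
  row <- pmin(pmax(row, 0), nr - 1)
  col <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(row), nr - 2)
  c0 <- pmin(floor(col), nc - 2)
  fr <- row - r0
  fc <- col - c0
  M[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1, c0 + 2)] * (1 - fr) * fc +
    M[cbind(r0 + 2, c0 + 1)] * fr * (1 - fc) +
    M[cbind(r0 + 2, c0 + 2)] * fr * fc
}

# Fill non-finite entries of M with values propagated from the nearest
# (4-connected graph distance) finite pixels, by iterative dilation. Used to
# extrapolate velocities defined only on the myocardial mask.
.nn_fill <- function(M) {
  while (anyNA(M) || any(!is.finite(M))) {
    bad <- !is.finite(M)
    if (!any(bad)) break
    shifted <- list(
      rbind(M[-1, , drop = FALSE], NA),
      rbind(NA, M[-nrow(M), , drop = FALSE]),
      cbind(M[, -1, drop = FALSE], NA),
      cbind(NA, M[, -ncol(M), drop = FALSE])
    )
    acc <- matrix(0, nrow(M), ncol(M))
    cnt <- matrix(0L, nrow(M), ncol(M))
    for (S in shifted) {
      ok <- is.finite(S)
      acc[ok] <- acc[ok] + S[ok]
      cnt[ok] <- cnt[ok] + 1L
    }
    fill <- bad & cnt > 0L
    if (!any(fill)) break  # isolated region; give up, caller zeroes the rest
    M[fill] <- acc[fill] / cnt[fill]
  }
  M[!is.finite(M)] <- 0
  M
}

# population standard deviation (divisor n)
.sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# local RNG scope: run expr with a given seed without disturbing the caller's
# RNG stream; seed = NULL leaves the global stream untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
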