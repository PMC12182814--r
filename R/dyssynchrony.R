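# Per-slice mechanical dyssynchrony statistics computed from segmental
# radial strain and strain-rate curves: sdTTP, maxTTP, SRCC, and RURE.

#' Time to peak strain per segment
#'
#' Time (ms, from end-diastole) of each segmental curve's maximum; ties are
#' broken to the earliest frame. A flat curve (zero range) has no peak and
#' yields `NA`.
#'
#' @param curves a [segment_curves()] object.
#' @return named numeric vector of TTP in ms.
#' @export
time_to_peak <- function(curves) {
  apply(curves$strain, 1, function(s) {
    if (diff(range(s)) == 0) return(NA_real_)
    (which.max(s) - 1) * curves$frame_duration_ms
  })
}

#' Standard deviation of time to peak (sdTTP)
#'
#' Population standard deviation (divisor n) of the segmental TTPs of one
#' slice, in ms. Higher values indicate more dyssynchronous contraction.
#'
#' @param ttp numeric vector of segmental TTPs (ms), possibly with `NA`s.
#' @return sdTTP in ms.
#' @export
sd_ttp <- function(ttp) {
  ttp <- ttp[!is.na(ttp)]
  if (length(ttp) < 2L)
    .stopf("sd_ttp needs at least 2 defined segmental TTPs (got %d)", length(ttp))
  .sd_pop(ttp)
}

#' Maximum time to peak
#'
#' @param ttp numeric vector of segmental TTPs (ms), possibly with `NA`s.
#' @return maximum defined TTP in ms.
#' @export
max_ttp <- function(ttp) {
  ttp <- ttp[!is.na(ttp)]
  if (length(ttp) == 0L) .stopf("no defined segmental TTPs")
  max(ttp)
}

# circular normalized cross-correlation lag between two curves.
# Returns the signed lag (frames) maximizing the normalized circular
# cross-correlation, searched over |lag| <= floor(n/2); ties are broken to
# the smallest |lag|, then to the positive lag.
.xcorr_lag <- function(a, b) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) return(NA_real_)
  lags <- -floor(n / 2):floor(n / 2)
  cc <- vapply(lags, function(l) {
    sum(a * b[(seq_len(n) - 1 + l) %% n + 1]) / denom
  }, numeric(1))
  ord <- order(abs(lags), -sign(lags))   # prefer small |lag|, then positive
  lags <- lags[ord]; cc <- cc[ord]
  lags[which.max(cc)]
}

#' Strain-rate cross-correlation lag statistic (SRCC)
#'
#' For every unordered pair of segments, the signed lag maximizing the
#' normalized circular cross-correlation of the two zero-mean strain-rate
#' curves is found (search bounded at half the cycle so lags stay
#' identifiable). SRCC is the mean of the absolute pairwise lags
#' (`agg = "mean"`, default) or their maximum (`agg = "max"`), converted to
#' ms. Perfectly synchronous slices give 0. Pairs involving a zero-variance
#' curve are skipped; if all pairs are skipped an error is raised.
#'
#' @param curves a [segment_curves()] object.
#' @param srcc_agg `"mean"` or `"max"` aggregation over segment pairs.
#' @return SRCC in ms.
#' @export
srcc <- function(curves, srcc_agg = c("mean", "max")) {
  srcc_agg <- match.arg(srcc_agg)
  sr <- curves$strain_rate
  m <- nrow(sr)
  if (m < 2L) .stopf("srcc needs at least 2 segments")
  lags <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    l <- .xcorr_lag(sr[i, ], sr[j, ])
    if (!is.na(l)) lags <- c(lags, abs(l))
  }
  if (length(lags) == 0L)
    .stopf("all segment pairs had zero-variance strain-rate curves")
  agg <- if (srcc_agg == "mean") mean(lags) else max(lags)
  agg * curves$frame_duration_ms
}

#' Radial uniformity ratio estimate (RURE)
#'
#' At every frame the segmental strain values, ordered by circumferential
#' position, are Fourier-transformed around the circumference. With `A0(t)`
#' and `A1(t)` the magnitudes of the order-0 and order-1 coefficients, the
#' default (time-summed) estimate is
#' `RURE = sum_t A0(t) / sum_t (A0(t) + A1(t))`,
#' over frames with a nonzero denominator; `rure_variant = "framewise"`
#' instead averages the per-frame ratios. RURE is 1 for perfectly uniform
#' contraction and approaches 0 for a pure first-harmonic pattern (one wall
#' thickening while the opposite wall thins). All-zero curves yield `NA`.
#'
#' @param curves a [segment_curves()] object (>= 4 segments).
#' @param rure_variant `"summed"` (default) or `"framewise"`.
#' @return RURE, dimensionless in `[0, 1]`.
#' @export
rure <- function(curves, rure_variant = c("summed", "framewise")) {
  rure_variant <- match.arg(rure_variant)
  s <- curves$strain
  m <- nrow(s)
  if (m < 4L) .stopf("rure needs at least 4 segments (got %d)", m)
  ph <- exp(-2i * pi * (seq_len(m) - 1) / m)
  a0 <- abs(colSums(s))
  a1 <- abs(colSums(s * ph))
  keep <- (a0 + a1) > 0
  if (!any(keep)) return(NA_real_)
  if (rure_variant == "summed") {
    sum(a0[keep]) / sum(a0[keep] + a1[keep])
  } else {
    mean(a0[keep] / (a0[keep] + a1[keep]))
  }
}

#' All four dyssynchrony statistics for one slice
#'
#' Bundles sdTTP, maxTTP, SRCC, and RURE (radial channel) for a slice. If
#' the curves are degenerate (flat strain everywhere), a record of `NA`s is
#' returned rather than an error.
#'
#' @param curves a [segment_curves()] object.
#' @inheritParams srcc
#' @inheritParams rure
#' @return one-row data frame of class `dyssynchrony_metrics` with columns
#'   `slice`, `sdTTP_ms`, `maxTTP_ms`, `SRCC_ms`, `RURE`.
#' @export
slice_metrics <- function(curves, srcc_agg = "mean", rure_variant = "summed") {
  ttp <- time_to_peak(curves)
  res <- data.frame(
    slice = curves$slice_level,
    sdTTP_ms = tryCatch(sd_ttp(ttp), error = function(e) NA_real_),
    maxTTP_ms = tryCatch(max_ttp(ttp), error = function(e) NA_real_),
    SRCC_ms = tryCatch(srcc(curves, srcc_agg), error = function(e) NA_real_),
    RURE = tryCatch(rure(curves, rure_variant), error = function(e) NA_real_)
  )
  class(res) <- c("dyssynchrony_metrics", "data.frame")
  res
}

#' Assemble the per-patient clustering feature vector from three slices
#'
#' Combines the segmental peak radial strains and per-slice dyssynchrony
#' statistics of an apical, mid, and basal slice into the canonical
#' 25-feature row (see [lv_feature_names()]).
#'
#' @param slices named list with elements `apical`, `mid`, `basal`, each as
#'   returned by [analyze_cine()] (needs `$summary` and `$dyssynchrony`).
#' @param patient_id identifier for the row.
#' @return one-row data frame: `patient_id`, 25 feature columns, plus
#'   `maxTTP_<slice>` extras.
#' @export
patient_features <- function(slices, patient_id = "patient") {
  stopifnot(all(c("apical", "mid", "basal") %in% names(slices)))
  row <- list(patient_id = patient_id)
  for (lv in c("apical", "mid", "basal")) {
    sm <- slices[[lv]]$summary$segments
    for (i in seq_len(nrow(sm)))
      row[[paste0("peakRS_", lv, "_", sm$segment[i])]] <- sm$peak_RS_pct[i]
    dy <- slices[[lv]]$dyssynchrony
    row[[paste0("sdTTP_", lv)]] <- dy$sdTTP_ms
    row[[paste0("SRCC_", lv)]] <- dy$SRCC_ms
    row[[paste0("RURE_", lv)]] <- dy$RURE
    row[[paste0("maxTTP_", lv)]] <- dy$maxTTP_ms
  }
  out <- as.data.frame(row)
  missing <- setdiff(lv_feature_names(), names(out))
  if (length(missing))
    .stopf("feature assembly is missing: %s", paste(missing, collapse = ", "))
  out
}
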