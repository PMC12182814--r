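#' AHA segment names for a short-axis slice level
#'
#' The American Heart Association 16-segment model partitions the left
#' ventricle into 6 basal, 6 mid-ventricular, and 4 apical segments (the apex
#' cap, segment 17, is excluded throughout this package). Segments are listed
#' in the order they are swept counterclockwise from the anterior reference
#' direction when the slice is viewed in the standard short-axis orientation
#' (anterior wall at the top, septum at image left).
#'
#' @param slice_level one of `"basal"`, `"mid"`, `"apical"`.
#' @return character vector of segment names (6 for basal/mid, 4 for apical).
#' @examples
#' aha_segments("apical")
#' @export
aha_segments <- function(slice_level = c("basal", "mid", "apical")) {
  slice_level <- match.arg(slice_level)
  if (slice_level == "apical") {
    c("anterior", "septal", "inferior", "lateral")
  } else {
    c("anterior", "anteroseptal", "inferoseptal",
      "inferior", "inferolateral", "anterolateral")
  }
}

#' Canonical feature schema for the patient-level clustering vector
#'
#' The clustering feature vector has 25 entries: 16 segmental peak radial
#' strains (in %) named `peakRS_<slice>_<segment>`, and the three per-slice
#' dyssynchrony statistics `sdTTP_<slice>` (ms), `SRCC_<slice>` (ms), and
#' `RURE_<slice>` (dimensionless). The maximum time-to-peak is computed by
#' the dyssynchrony stage but is not part of the default clustering vector.
#'
#' @return character vector of 25 feature names, in canonical order.
#' @export
lv_feature_names <- function() {
  segs <- unlist(lapply(c("apical", "mid", "basal"), function(lv) {
    paste0("peakRS_", lv, "_", aha_segments(lv))
  }))
  c(segs,
    paste0("sdTTP_", c("apical", "mid", "basal")),
    paste0("SRCC_", c("apical", "mid", "basal")),
    paste0("RURE_", c("apical", "mid", "basal")))
}

# number of angular sectors for a slice level
.n_sectors_for_level <- function(slice_level) {
  if (identical(slice_level, "apical")) 4L else 6L
}
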