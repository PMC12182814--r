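# Shared fixtures built in code. Expensive phantom analyses are cached per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the reference uniform noiseless phantom (the strain-recovery condition)
uniform_phantom <- function() cached("uniform_phantom", {
  generate_phantom(phantom_spec())
})

uniform_analysis <- function() cached("uniform_analysis", {
  analyze_cine(uniform_phantom()$cine)
})

# build a segment_curves object directly from a strain matrix (segments x
# frames); strain rate by the same centered-difference convention
make_curves <- function(strain, frame_duration_ms = 25, slice_level = "mid",
                        labels = NULL) {
  m <- nrow(strain); nf <- ncol(strain)
  if (is.null(labels)) labels <- aha_segments(slice_level)[seq_len(m)]
  dt_s <- frame_duration_ms / 1000
  rate <- t(apply(strain, 1, function(x) {
    n <- length(x); d <- numeric(n)
    d[1] <- (x[2] - x[1]) / dt_s
    d[n] <- (x[n] - x[n - 1]) / dt_s
    if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt_s)
    d
  }))
  structure(list(strain = strain, strain_rate = rate,
                 times_ms = (seq_len(nf) - 1) * frame_duration_ms,
                 frame_duration_ms = frame_duration_ms,
                 labels = labels, n_px = rep(1L, m),
                 slice_level = slice_level, channel = "radial"),
            class = "segment_curves")
}

# four well-separated Gaussian blobs in 2-D
make_blobs <- function(n_per = 10, centers = rbind(c(0, 0), c(10, 0),
                                                  c(0, 10), c(10, 10)),
                       sd = 0.5, seed = 99) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}
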