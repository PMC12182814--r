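# sdTTP, maxTTP, SRCC, and RURE on constructed segmental curves.

# a smooth single-peaked activation curve, circularly shifted by `lag` frames
bump <- function(nf, lag = 0, amp = 0.3) {
  w <- amp * sin(pi * (0:(nf - 1)) / nf)^2
  w[((seq_len(nf) - 1 - lag) %% nf) + 1]
}

test_that("time to peak follows the argmax-times-dt rule", {
  nf <- 30
  s <- rbind(bump(nf, 0), bump(nf, 0))
  s[1, ] <- 0; s[1, 13] <- 0.5          # peak at frame 12
  cv <- make_curves(s, frame_duration_ms = 33)
  ttp <- time_to_peak(cv)
  expect_equal(unname(ttp[1]), 396)
  # all segments peaking together -> identical TTPs
  cv2 <- make_curves(rbind(bump(nf), bump(nf), bump(nf)), 25)
  expect_equal(length(unique(time_to_peak(cv2))), 1L)
  # flat curve -> missing
  cv3 <- make_curves(rbind(rep(0, nf), bump(nf)), 25)
  expect_true(is.na(time_to_peak(cv3)[1]))
})

test_that("sdTTP is the population SD and maxTTP the maximum", {
  expect_equal(sd_ttp(c(400, 600)), 100)
  expect_equal(sd_ttp(rep(480, 6)), 0)
  expect_error(sd_ttp(c(500, NA, NA)), "at least 2")
  expect_equal(max_ttp(c(400, 600)), 600)
  expect_equal(max_ttp(rep(480, 4)), 480)
})

test_that("SRCC recovers constructed pairwise lags", {
  nf <- 40
  # identical curves in all segments -> 0 ms
  cv <- make_curves(rbind(bump(nf), bump(nf), bump(nf), bump(nf)), 40,
                    slice_level = "apical")
  expect_equal(srcc(cv), 0)
  # one curve shifted by exactly 3 frames at dt = 40 ms -> 120 ms
  cv2 <- make_curves(rbind(bump(nf), bump(nf, 3)), 40)
  expect_equal(srcc(cv2), 120)
  expect_equal(srcc(cv2, srcc_agg = "max"), 120)
  # zero-variance curves are skipped; all-flat errors
  cv3 <- make_curves(rbind(rep(0, nf), rep(0, nf)), 40)
  expect_error(srcc(cv3), "zero-variance")
})

test_that("SRCC lags agree with a brute-force cross-correlation oracle", {
  set.seed(31)
  nf <- 36
  for (rep in 1:5) {
    a <- stats::filter(rnorm(nf), rep(1 / 4, 4), circular = TRUE)
    b <- bump(nf, sample(0:8, 1)) + rnorm(nf, sd = 0.02)
    expect_equal(lvmech:::.xcorr_lag(as.numeric(a), as.numeric(b)),
                 xcorr_lag_oracle(as.numeric(a), as.numeric(b)))
  }
})

test_that("RURE hits its analytic extremes and matches a DFT oracle", {
  nf <- 20
  th <- 2 * pi * (0:5) / 6
  # identical curves -> 1
  cv <- make_curves(matrix(rep(bump(nf), 6), 6, byrow = TRUE), 25)
  expect_equal(rure(cv), 1)
  # pure first harmonic around the ring -> 0
  s1 <- outer(cos(th), bump(nf))
  expect_equal(rure(make_curves(s1, 25)), 0, tolerance = 1e-12)
  # mixed uniform + first harmonic: ratio known in closed form (6/7)
  s2 <- matrix(0.3 + 0.1 * cos(th), 6, nf)
  expect_equal(rure(make_curves(s2, 25)), 6 / 7, tolerance = 1e-12)
  expect_equal(rure(make_curves(s2, 25)), rure_oracle(s2), tolerance = 1e-12)
  # random curves against the fft oracle, both variants' shared pieces
  set.seed(7)
  s3 <- matrix(abs(rnorm(6 * nf, 0.2, 0.1)), 6)
  expect_equal(rure(make_curves(s3, 25)), rure_oracle(s3), tolerance = 1e-12)
})

test_that("RURE is invariant to rotating the segment order", {
  set.seed(12)
  s <- matrix(abs(rnorm(6 * 15, 0.2, 0.1)), 6)
  r0 <- rure(make_curves(s, 25))
  for (shift in 1:5) {
    rs <- rure(make_curves(s[c((shift + 1):6, 1:shift), ], 25))
    expect_equal(rs, r0, tolerance = 1e-12)
  }
})

test_that("dyssynchrony metrics are scale invariant and delay monotone", {
  nf <- 40
  s <- rbind(bump(nf), bump(nf, 2), bump(nf, 5), bump(nf, 1))
  cv1 <- make_curves(s, 25, slice_level = "apical")
  cv2 <- make_curves(3.7 * s, 25, slice_level = "apical")
  expect_equal(time_to_peak(cv1), time_to_peak(cv2))
  expect_equal(srcc(cv1), srcc(cv2))
  expect_equal(rure(cv1), rure(cv2), tolerance = 1e-12)

  sd_at <- sr_at <- numeric(5)
  for (d in 0:4) {
    cvd <- make_curves(rbind(bump(nf), bump(nf), bump(nf),
                             bump(nf), bump(nf), bump(nf, d)), 25)
    ttp <- time_to_peak(cvd)
    sd_at[d + 1] <- sd_ttp(ttp)
    sr_at[d + 1] <- srcc(cvd)
  }
  expect_true(all(diff(sd_at) >= 0))
  expect_true(all(diff(sr_at) >= 0))
})

test_that("slice_metrics bundles the slice statistics and degrades to NA", {
  an <- uniform_analysis()
  dy <- an$dyssynchrony
  expect_equal(dy$sdTTP_ms, 0)
  expect_equal(dy$maxTTP_ms, 500)
  expect_equal(dy$SRCC_ms, 0)
  expect_gt(dy$RURE, 0.99)
  flat <- make_curves(matrix(0, 6, 20), 25)
  df <- slice_metrics(flat)
  expect_true(all(is.na(df[, c("sdTTP_ms", "maxTTP_ms", "SRCC_ms", "RURE")])))
})

test_that("patient feature assembly emits the canonical 25-column schema", {
  mk <- function(level) {
    m <- length(aha_segments(level))
    list(summary = list(segments = data.frame(
           slice = level, segment = aha_segments(level),
           peak_RS_pct = seq_len(m) * 10, TTP_ms = 400)),
         dyssynchrony = data.frame(slice = level, sdTTP_ms = 50,
                                   maxTTP_ms = 500, SRCC_ms = 80, RURE = 0.9))
  }
  row <- patient_features(list(apical = mk("apical"), mid = mk("mid"),
                               basal = mk("basal")), "P1")
  expect_true(all(lv_feature_names() %in% names(row)))
  expect_equal(row$peakRS_apical_septal, 20)
  expect_equal(row$RURE_basal, 0.9)
})
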