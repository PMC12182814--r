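# Tracking, deformation-gradient strain, AHA segmentation, segment curves.

# a small static cine with a prescribed constant velocity field
flow_cine <- function(v_row = 0, v_col = 0, n = 32, sp = 1.5, nf = 11,
                      dt = 50, r0 = 10, r1 = 16) {
  c0 <- (n - 1) / 2
  col <- matrix(rep(0:(n - 1), each = n), n)
  row <- matrix(rep(0:(n - 1), times = n), n)
  rho <- sqrt(((col - c0) * sp)^2 + ((c0 - row) * sp)^2)
  mask <- rho >= r0 & rho <= r1
  vel <- array(0, c(nf, n, n, 2))
  vel[, , , 1] <- v_row
  vel[, , , 2] <- v_col
  velocity_cine(vel, mask, rep(sp, 2), dt)
}

test_that("zero velocity yields identity flow and zero strain", {
  cine <- flow_cine(0, 0)
  traj <- track_displacements(cine)
  expect_equal(traj$pos[, , dim(traj$pos)[3]], traj$pos[, , 1])
  maps <- compute_strain(traj)
  expect_equal(max(abs(maps$radial[maps$valid, ])), 0, tolerance = 1e-12)
  expect_equal(max(abs(maps$circumferential[maps$valid, ])), 0,
               tolerance = 1e-12)
})

test_that("constant velocity produces the expected linear displacement", {
  # 1 mm/s along +col for 10 steps of 50 ms -> 0.5 mm in x
  cine <- flow_cine(v_col = 1, nf = 11, dt = 50)
  traj <- track_displacements(cine)
  dx <- traj$pos[, 1, 11] - traj$pos[, 1, 1]
  dy <- traj$pos[, 2, 11] - traj$pos[, 2, 1]
  expect_equal(unname(dx), rep(0.5, length(dx)), tolerance = 1e-9)
  expect_equal(max(abs(dy)), 0)
})

test_that("rigid rotation of the tracked points produces zero strain", {
  cine <- flow_cine(0, 0)
  traj <- track_displacements(cine)
  ang <- 10 * pi / 180
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  for (k in 2:dim(traj$pos)[3]) traj$pos[, , k] <- traj$pos[, , 1] %*% Rm
  maps <- compute_strain(traj)
  expect_lt(max(abs(maps$radial[maps$valid, ])), 1e-9)
  expect_lt(max(abs(maps$circumferential[maps$valid, ])), 1e-9)
})

test_that("tracked endocardial radius matches the analytic contraction", {
  ph <- uniform_phantom()   # r_endo0 = 20 mm, c = 0.25, 40 frames, 0.5 mm
  traj <- track_displacements(ph$cine)
  R0 <- sqrt(rowSums(traj$pos[, , 1]^2))
  endo <- R0 < 20.3
  k_peak <- 21   # t = T/2
  r_peak <- sqrt(rowSums(traj$pos[endo, , k_peak]^2))
  expect_lt(abs(median(r_peak) - 15) / 15, 0.02)
})

test_that("mid-wall pixel strain matches the analytic truth within 0.03", {
  ph <- uniform_phantom()
  an <- uniform_analysis()
  traj <- track_displacements(ph$cine)
  maps <- compute_strain(traj)
  R0 <- sqrt(rowSums(traj$pos[, , 1]^2))
  mid <- abs(R0 - 24) < 0.5 & maps$valid
  truth <- ph$truth$curve[1, ]
  err <- abs(colMeans(maps$radial[mid, ]) - truth)
  expect_lt(max(err), 0.03)
})

test_that("segment maps partition the mask with the AHA label sets", {
  cine <- flow_cine()
  geo <- default_geometry(cine)
  sm <- build_segment_map(cine, geo)
  expect_setequal(sm$labels, aha_segments("mid"))
  expect_true(all(tabulate(sm$segment, 6) >= 1))
  expect_equal(length(sm$segment), sum(cine$ed_mask))

  apical <- flow_cine()
  apical$slice_level <- "apical"
  sma <- build_segment_map(apical, default_geometry(apical))
  expect_equal(length(unique(sma$segment)), 4L)
  expect_setequal(sma$labels, c("anterior", "septal", "inferior", "lateral"))
})

test_that("rotating the anterior reference by 60 degrees permutes labels cyclically", {
  cine <- flow_cine()
  g0 <- default_geometry(cine)
  g1 <- slice_geometry(g0$centroid, g0$anterior_reference_angle_rad + pi / 3,
                       "mid")
  s0 <- build_segment_map(cine, g0)$segment
  s1 <- build_segment_map(cine, g1)$segment
  # a pixel assigned sector s under the rotated reference was sector s+1
  expect_equal(s0, (s1 %% 6L) + 1L)
})

test_that("segment averaging and the summary follow their defining rules", {
  # spatially uniform synthetic strain field -> every segment equals it
  cine <- flow_cine()
  traj <- track_displacements(cine)
  maps <- compute_strain(traj)
  nf <- dim(traj$pos)[3]
  wave <- 0.2 * sin(pi * (seq_len(nf) - 1) / (nf - 1))^2
  maps$radial <- matrix(wave, nrow(maps$radial), nf, byrow = TRUE)
  segmap <- build_segment_map(cine)
  curves <- segment_curves(maps, segmap)
  for (s in seq_len(6)) expect_equal(unname(curves$strain[s, ]), wave)

  sm <- strain_summary(make_curves(rbind(c(0, .1, .3, .2)),
                                   frame_duration_ms = 50, labels = "anterior"))
  expect_equal(sm$segments$peak_RS_pct, 30)
  expect_equal(sm$segments$TTP_ms, 100)
  # equal maxima -> earliest frame wins
  sm2 <- strain_summary(make_curves(rbind(c(0, .3, .1, .3)),
                                    frame_duration_ms = 50, labels = "anterior"))
  expect_equal(sm2$segments$TTP_ms, 50)
})

test_that("a segment with no valid pixels is an error naming the segment", {
  cine <- flow_cine()
  traj <- track_displacements(cine)
  maps <- compute_strain(traj)
  segmap <- build_segment_map(cine)
  maps$valid[segmap$segment == 3] <- FALSE
  expect_error(segment_curves(maps, segmap), "inferoseptal")
})

test_that("uniform phantom: global RS equals each segmental peak within 1 pp", {
  an <- uniform_analysis()
  peaks <- an$summary$segments$peak_RS_pct
  expect_lt(max(abs(peaks - an$summary$global_RS_pct)), 1)
})

test_that("segmental curves are equivariant to a 90-degree image rotation", {
  ph <- generate_phantom(phantom_spec(
    grid_size = 64, pixel_spacing_mm = 1, n_frames = 20, frame_duration_ms = 50,
    r_endo0_mm = 14, r_epi0_mm = 22,
    contraction_fraction = c(0.25, 0.1, 0.2, 0.15, 0.25, 0.2)))
  cine <- ph$cine
  # rotate the image 90 deg counterclockwise: new[r, c] = old[c, N+1-r];
  # vectors rotate with it: v_row' = -v_col, v_col' = v_row
  n <- dim(cine$velocity)[2]
  rot_mat <- function(M) t(M)[n:1, ]
  vel2 <- array(0, dim(cine$velocity))
  for (k in seq_len(dim(cine$velocity)[1])) {
    vel2[k, , , 1] <- -rot_mat(cine$velocity[k, , , 2])
    vel2[k, , , 2] <- rot_mat(cine$velocity[k, , , 1])
  }
  cine2 <- velocity_cine(vel2, rot_mat(cine$ed_mask), cine$pixel_spacing_mm,
                         cine$frame_duration_ms, cine$slice_level)
  g1 <- default_geometry(cine)
  g2 <- slice_geometry(default_geometry(cine2)$centroid,
                       g1$anterior_reference_angle_rad + pi / 2, "mid")
  c1 <- segment_curves(compute_strain(track_displacements(cine, g1), g1),
                       build_segment_map(cine, g1))
  c2 <- segment_curves(compute_strain(track_displacements(cine2, g2), g2),
                       build_segment_map(cine2, g2))
  expect_lt(max(abs(c1$strain - c2$strain)), 0.01)
})

test_that("strain error against truth shrinks with finer resolution", {
  err_at <- function(sp, nf) {
    ph <- generate_phantom(phantom_spec(
      grid_size = round(64 / sp), pixel_spacing_mm = sp, n_frames = nf,
      frame_duration_ms = 1000 / nf, r_endo0_mm = 14, r_epi0_mm = 22,
      contraction_fraction = 0.2))
    an <- analyze_cine(ph$cine)
    max(abs(sweep(an$curves$strain, 2, ph$truth$curve[1, ])))
  }
  coarse <- err_at(1.0, 20)
  fine <- err_at(0.5, 40)
  expect_lt(fine, coarse)
})

test_that("moderate velocity noise moves segmental peaks by under 3 pp", {
  ph <- uniform_phantom()
  peak_v <- max(abs(ph$cine$velocity))
  spec_n <- phantom_spec(noise_sd_mm_s = 0.05 * peak_v, seed = 11)
  an_n <- analyze_cine(generate_phantom(spec_n)$cine)
  clean <- uniform_analysis()$summary$segments$peak_RS_pct
  noisy <- an_n$summary$segments$peak_RS_pct
  expect_lt(max(abs(noisy - clean)), 3)
})

test_that("strain rate reintegrates to strain", {
  # exactly, for a linear ramp (centered differences and the trapezoid rule
  # are both exact there) ...
  lin <- make_curves(rbind(seq(0, 0.3, length.out = 16)),
                     frame_duration_ms = 40, labels = "anterior")
  reint <- function(cv) {
    dt_s <- cv$frame_duration_ms / 1000
    r <- cv$strain_rate[1, ]
    c(0, cumsum((r[-length(r)] + r[-1]) / 2 * dt_s))
  }
  expect_equal(reint(lin), unname(lin$strain[1, ]), tolerance = 1e-12)
  # ... and to discretization accuracy for a smooth activation waveform
  nf <- 200
  smooth <- make_curves(rbind(0.2 * sin(pi * (0:(nf - 1)) / nf)^2),
                        frame_duration_ms = 5, labels = "anterior")
  expect_lt(max(abs(reint(smooth) - smooth$strain[1, ])), 1e-4)
})
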