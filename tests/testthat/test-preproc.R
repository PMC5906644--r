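make_textured_stack <- function(nt = 4, nr = 64, nc = 64, seed = 1,
                                shifts = NULL) {
  set.seed(seed)
  base <- matrix(runif(nr * nc, 0, 0.2), nr, nc)
  base[20:32, 22:44] <- base[20:32, 22:44] + matrix(runif(13 * 23), 13)
  frames <- array(0, dim = c(nr, nc, nt))
  for (f in seq_len(nt)) {
    frames[, , f] <- if (is.null(shifts) || all(shifts[f, ] == 0)) base else
      ulmtrack:::shift_image(base, shifts[f, ])
  }
  frame_stack(frames, 50, c(11.6, 11.6))
}

test_that("motion estimation recovers known sub-pixel shifts", {
  # zero true motion: all displacements zero
  st0 <- make_textured_stack(3)
  m0 <- estimate_rigid_motion(st0, upsample = 4)
  expect_equal(m0$d_ax_um, rep(0, 3))
  expect_equal(m0$d_lat_um, rep(0, 3))

  # known shift on frame 2: (12, -8) um ~ (1.03, -0.69) px, recovered to
  # within half an upsampled pixel (11.6/4/2 = 1.45 um)
  sh <- rbind(c(0, 0), c(12, -8) / 11.6, c(0, 0))
  st <- make_textured_stack(3, shifts = sh)
  m <- estimate_rigid_motion(st, upsample = 4)
  expect_lt(abs(m$d_ax_um[2] - 12), 11.6 / 4 / 2)
  expect_lt(abs(m$d_lat_um[2] + 8), 11.6 / 4 / 2)
  # estimates live on the 1/4-pixel grid: 2.9 um quantum
  expect_equal(m$d_ax_um[2] %% (11.6 / 4), 0, tolerance = 1e-9)

  # blank frame: flagged excluded
  stb <- make_textured_stack(3)
  stb$frames[, , 3] <- 0
  mb <- estimate_rigid_motion(stb)
  expect_true(mb$excluded[3])
})

test_that("frame exclusion cuts exactly the injected breathing spikes", {
  set.seed(21)
  nt <- 40
  spikes <- c(7, 15, 22, 30, 38)
  prof <- make_motion_profile(nt, spike_frames = spikes,
                              spike_amplitude = 80, jitter_sd = 2, seed = 13)
  seg <- vessel_segment(c(300, 200), c(300, 1000), radius = 15,
                        flow_speed = 0.8)
  truth <- simulate_bubbles(list(seg), duration = nt / 50, frame_rate = 50,
                            bubble_rate = 5, min_separation = 300, seed = 2)
  truth$n_frames <- nt
  truth$bubbles <- truth$bubbles[truth$bubbles$frame <= nt, ]
  st <- render_frames(truth, c(600, 1200), background_amplitude = 0.4,
                      noise_sigma = 0.02, motion_profile = prof,
                      decorr_frames = spikes, seed = 3)
  m <- estimate_rigid_motion(st, upsample = 4)
  # vacuous limits exclude nothing
  m_vac <- exclude_frames(m, displacement_limit = Inf,
                          correlation_floor = -1)
  expect_equal(sum(m_vac$excluded), 0)
  m_ex <- exclude_frames(m, displacement_limit = 40,
                         correlation_floor = 0.8)
  expect_setequal(which(m_ex$excluded), spikes)
  # retained-frame displacement within the limit
  mag <- sqrt(m_ex$d_ax_um^2 + m_ex$d_lat_um^2)
  expect_true(all(mag[!m_ex$excluded] <= 40))
  # all-excluded is a hard error
  expect_error(exclude_frames(m, displacement_limit = -1,
                              correlation_floor = 2), "no usable frames")
})

test_that("motion compensation stabilizes the scene", {
  # identity on zero displacements
  st <- make_textured_stack(3)
  m <- estimate_rigid_motion(st)
  expect_equal(compensate_motion(st, m)$frames, st$frames)

  # known motion on a speckle scene: residual background frame-difference
  # energy shrinks strongly after compensation
  sh_px <- rbind(c(0, 0), c(1.5, -2.25), c(-0.75, 1.25))
  seg <- vessel_segment(c(302.5, 402.5), c(302.5, 900), radius = 10,
                        flow_speed = 0)
  empty <- simulate_bubbles(list(seg), duration = 3 / 50, frame_rate = 50,
                            bubble_rate = 0, seed = 2)
  stm <- render_frames(empty, c(600, 1200), background_amplitude = 0.4,
                       motion_profile = sh_px * 11.6, seed = 4)
  mm <- estimate_rigid_motion(stm, upsample = 8)
  comp <- compensate_motion(stm, mm)
  energy <- function(a) sum((a[, , 2] - a[, , 1])^2) +
    sum((a[, , 3] - a[, , 1])^2)
  expect_lt(energy(comp$frames), 0.2 * energy(stm$frames))

  # a static bubble under known motion: compensated centroid stationary
  # to < 1 um
  truth <- structure(
    list(segments = list(seg),
         bubbles = data.frame(bubble = 1L, frame = 1:3, t = (0:2) / 50,
                              ax_um = 302.5, lat_um = 402.5, segment = 1L),
         n_frames = 3L, frame_rate = 50, destruction_frame = NULL,
         dead_window = 0),
    class = "phantom_truth")
  stb <- render_frames(truth, c(600, 1200), background_amplitude = 0,
                       motion_profile = sh_px * 11.6, seed = 4)
  mb <- estimate_rigid_motion(stb, upsample = 8)
  compb <- compensate_motion(stb, mb)
  centroid <- function(img) {
    ax <- (seq_len(nrow(img)) - 1) * 11.6
    lat <- (seq_len(ncol(img)) - 1) * 11.6
    w <- img
    w[w < 0.05] <- 0
    c(sum(w * ax) / sum(w), sum(t(w) * lat) / sum(w))
  }
  cents <- vapply(1:3, function(f) centroid(compb$frames[, , f]), numeric(2))
  expect_lt(max(abs(cents[1, ] - cents[1, 1])), 1)
  expect_lt(max(abs(cents[2, ] - cents[2, 1])), 1)
})

test_that("temporal rank background takes the rank-th smallest over the window", {
  # constant sequence: background == the constant
  fr <- array(0.7, dim = c(4, 4, 25))
  st <- frame_stack(fr, 50, c(10, 10))
  bg <- temporal_rank_background(st, rank = 3, half_window = 10)
  expect_equal(bg$frames, fr)

  # transient: pixel values 0,0,0,5,9,... with rank 3 -> background 0
  v <- c(0, 0, 0, 5, 9, rep(0, 20))
  fr2 <- array(rep(v, each = 4), dim = c(2, 2, 25))
  st2 <- frame_stack(fr2, 50, c(10, 10))
  bg2 <- temporal_rank_background(st2, rank = 3, half_window = 10)
  expect_equal(bg2$frames[1, 1, 4], 0)
  # independent oracle at an arbitrary frame: sorted window, 3rd smallest
  f <- 12
  win <- v[max(1, f - 10):min(25, f + 10)]
  expect_equal(bg2$frames[2, 2, f], sort(win)[3])

  # bubble-free speckle phantom: background equals the static speckle field
  seg <- vessel_segment(c(100, 100), c(100, 500), radius = 5, flow_speed = 1)
  truth <- simulate_bubbles(list(seg), duration = 0.5, bubble_rate = 0,
                            seed = 1)
  sp <- render_frames(truth, c(200, 600), background_amplitude = 0.5,
                      seed = 9)
  bg3 <- temporal_rank_background(sp)
  expect_equal(bg3$frames, sp$frames)
  expect_error(temporal_rank_background(st, rank = 30), "rank")
})

test_that("foreground is the clipped difference and isolates transients", {
  st <- make_textured_stack(3)
  bg <- temporal_rank_background(st, rank = 1, half_window = 1)
  fg0 <- foreground(st, bg)
  expect_equal(max(abs(fg0$frames)), 0) # static scene: zero foreground

  st2 <- st
  st2$frames[10, 10, 2] <- st2$frames[10, 10, 2] + 3
  fg <- foreground(st2, bg)
  expect_true(all(fg$frames >= 0))
  expect_equal(which(fg$frames > 1), which(fg$frames == fg$frames[10, 10, 2]))
  bad <- frame_stack(array(0, c(2, 2, 2)), 50, c(1, 1))
  expect_error(foreground(st, bad), "shape")
})

test_that("destruction calibration yields zero detections in the dead window", {
  seg <- vessel_segment(c(300, 200), c(300, 1000), radius = 15,
                        flow_speed = 0.8)
  truth <- simulate_bubbles(list(seg), duration = 4, frame_rate = 50,
                            bubble_rate = 8, destruction_frame = 100,
                            dead_window = 10, min_separation = 300, seed = 5)
  st <- render_frames(truth, c(600, 1200), background_amplitude = 0.3,
                      noise_sigma = 0.03, seed = 6)
  bg <- temporal_rank_background(st)
  fg <- foreground(st, bg)
  thr <- calibrate_threshold(fg, destruction_frame = 100, dead_window = 10)
  # threshold just above the dead-window max
  m <- max(fg$frames[, , 100:109])
  expect_gt(thr, m)
  expect_lt(thr, m * 1.001 + 1e-6)
  det <- detect_bubbles(fg, thr, min_pixels = 1)
  expect_equal(sum(det$detections$frame %in% 100:109), 0)
  # all-zero dead window: threshold collapses to just above zero
  fg0 <- fg
  fg0$frames[, , 100:109] <- 0
  expect_lt(calibrate_threshold(fg0, 100, 10), 1e-6)
  # fallback percentile rule warns
  fgn <- fg; fgn$destruction_frame <- NULL
  expect_warning(calibrate_threshold(fgn, NULL), "percentile")
})

test_that("detection localizes sub-pixel and is monotone in the threshold", {
  ph <- straight_vessel_phantom(duration = 1, seed = 12)
  det <- detect_bubbles(ph$stack, threshold = 0.1, min_pixels = 2)
  D <- match_detections_to_truth(det, ph$truth)
  # zero-noise: perfect recall, sub-0.1-pixel localization
  expect_equal(nrow(D), nrow(ph$truth$bubbles))
  expect_lt(mean(D$truth_err), 0.1 * 11.6)

  # symmetric blob centred exactly on a pixel: centroid at that pixel
  img <- array(0, dim = c(21, 21, 2))
  g <- dnorm(-5:5, sd = 1.5); blob <- outer(g, g)
  img[6:16, 6:16, 1] <- blob
  st <- frame_stack(img, 50, c(10, 10))
  d1 <- detect_bubbles(st, threshold = 1e-4, min_pixels = 1)
  expect_equal(d1$detections$ax_um, (11 - 1) * 10)
  expect_equal(d1$detections$lat_um, (11 - 1) * 10)

  # two well-separated blobs -> two detections
  img2 <- img
  img2[1:11, 1:11, 2] <- blob
  img2[11:21, 11:21, 2] <- img2[11:21, 11:21, 2] + blob
  st2 <- frame_stack(img2, 50, c(10, 10))
  d2 <- detect_bubbles(st2, threshold = 1e-3, min_pixels = 1)
  expect_equal(sum(d2$detections$frame == 2), 2)

  # raising the threshold never increases the per-frame count
  counts <- function(thr) {
    d <- detect_bubbles(ph$stack, thr, min_pixels = 2)$detections
    tabulate(d$frame, nbins = ph$truth$n_frames)
  }
  thrs <- c(0.05, 0.1, 0.3, 0.6, 0.9)
  cc <- vapply(thrs, counts, numeric(ph$truth$n_frames))
  for (k in seq_len(length(thrs) - 1)) {
    expect_true(all(cc[, k + 1] <= cc[, k]))
  }
  expect_error(detect_bubbles(ph$stack, 0.1,
                              roi = matrix(FALSE, 96, 121)), "ROI")
})

test_that("ROI polygons rasterize by the even-odd rule", {
  sq <- rbind(c(20, 20), c(20, 80), c(80, 80), c(80, 20))
  m <- rasterize_roi(sq, c(10, 10), c(10, 10))
  expect_true(m[4, 4]) # centre (30,30)
  expect_false(m[1, 1]) # (0,0) outside
  expect_equal(sum(m), 36) # centres 20..70 in both axes
})
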