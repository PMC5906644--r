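test_that("association scores match an independent R reference", {
  p <- motion_model_params()
  # one 2-detection track: closed-form Gaussian innovation
  det <- data.frame(frame = c(1L, 2L), ax_um = c(100, 112),
                    lat_um = c(200, 205))
  ll <- association_log_likelihood(list(c(1L, 2L)), det, p, frame_rate = 50)
  area <- bbox_area(det)
  v0 <- p$max_speed * 1000 / 50
  S <- 2 * p$measurement_noise_sigma^2 + v0^2 + p$process_noise_sigma^2 / 3
  hand <- -log(area) + sum(dnorm(c(12, 5), 0, sqrt(S), log = TRUE))
  expect_equal(ll, hand, tolerance = 1e-12)

  # random longer associations against the reference Kalman implementation
  set.seed(33)
  for (rep in 1:5) {
    n <- 12
    dd <- data.frame(frame = sort(sample(1:6, n, replace = TRUE)),
                     ax_um = runif(n, 0, 500), lat_um = runif(n, 0, 500))
    dd <- dd[order(dd$frame), ]
    # build two arbitrary frame-increasing tracks
    tr1 <- which(!duplicated(dd$frame))[1:3]
    left <- setdiff(seq_len(n), tr1)
    tr2 <- left[!duplicated(dd$frame[left])][1:2]
    tracks <- list(as.integer(tr1), as.integer(tr2))
    expect_equal(
      association_log_likelihood(tracks, dd, p, frame_rate = 50),
      ref_log_likelihood(tracks, dd, p, 50, bbox_area(dd)),
      tolerance = 1e-10)
    expect_equal(
      association_log_prior(tracks, dd, p, frame_rate = 50),
      ref_log_prior(tracks, dd, p),
      tolerance = 1e-10)
  }
})

test_that("a detection at the predicted position scores the Gaussian maximum", {
  p <- motion_model_params()
  base <- data.frame(frame = 1:3, ax_um = c(0, 20, 40) + 500,
                     lat_um = rep(500, 3))
  pad <- data.frame(frame = 1L, ax_um = c(0, 1000), lat_um = c(0, 1000))
  exact <- rbind(base, pad)
  off <- exact; off$ax_um[3] <- 540 + 7 # third detection off the prediction
  tr <- list(c(1L, 2L, 3L))
  expect_gt(association_log_likelihood(tr, exact, p, 50),
            association_log_likelihood(tr, off, p, 50))
})

test_that("the prior responds to rates and missed detections as designed", {
  det <- data.frame(frame = c(1L, 2L, 3L), ax_um = c(0, 20, 40),
                    lat_um = c(0, 0, 0))
  track <- list(c(1L, 2L, 3L))
  # empty association: finite prior
  expect_true(is.finite(association_log_prior(
    list(), det[0, ], motion_model_params(), frame_rate = 50)))
  # rising false-alarm rate monotonically favours the all-false-alarm state
  gaps <- vapply(c(0.1, 0.5, 1, 2, 5), function(lf) {
    p <- motion_model_params(false_alarm_rate = lf)
    association_log_prior(list(), det, p, frame_rate = 50) -
      association_log_prior(track, det, p, frame_rate = 50)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  # interior misses lower the prior when p_detect > 0.5
  p <- motion_model_params(p_detect = 0.9)
  det2 <- data.frame(frame = c(1L, 3L, 5L), ax_um = c(0, 40, 80),
                     lat_um = c(0, 0, 0))
  expect_lt(association_log_prior(list(c(1L, 2L, 3L)), det2, p, 50),
            association_log_prior(track, det, p, 50))
})

test_that("an unambiguous bubble yields a single full-length track", {
  p <- motion_model_params()
  det <- data.frame(frame = 1:5, ax_um = seq(100, 180, 20),
                    lat_um = rep(500, 5))
  det <- rbind(det, data.frame(frame = 1L, ax_um = 950, lat_um = 950))
  mc <- run_mcmcda(det, p, n_iterations = 20000, frame_rate = 50, seed = 1)
  expect_equal(length(mc$tracks), 1)
  expect_equal(sort(mc$tracks[[1]]), 1:5)
  # reported posterior never below the cold start
  expect_gte(mc$log_posterior, attr(mc, "initial_log_posterior"))
  # seeded determinism
  mc2 <- run_mcmcda(det, p, n_iterations = 20000, frame_rate = 50, seed = 1)
  expect_identical(mc$tracks, mc2$tracks)
  expect_equal(mc$log_posterior, mc2$log_posterior)
})

test_that("crossing bubbles resolve to the straight continuation, not the nearest-neighbour swap", {
  p <- motion_model_params()
  axA <- c(0, 60, 120, 180); axB <- c(180, 120, 60, 0)
  latA <- c(0, 20, 40, 60); latB <- c(5, 25, 45, 65)
  d <- data.frame(frame = rep(1:4, each = 2),
                  ax_um = c(rbind(axA, axB)) + 400,
                  lat_um = c(rbind(latA, latB)) + 400)
  d <- rbind(d, data.frame(frame = c(1, 1), ax_um = c(0, 1000),
                           lat_um = c(0, 1000)))
  straight <- list(c(1L, 3L, 5L, 7L), c(2L, 4L, 6L, 8L))
  swap <- list(c(1L, 3L, 6L, 8L), c(2L, 4L, 5L, 7L))
  ps <- association_log_posterior(straight, d, p, 50)
  pw <- association_log_posterior(swap, d, p, 50)
  expect_gt(ps, pw)
  ex <- exhaustive_map(d, p, frame_rate = 50)
  expect_identical(lapply(ex$tracks, as.integer), straight)
  mc <- run_mcmcda(d, p, n_iterations = 30000, frame_rate = 50, seed = 2)
  expect_identical(mc$tracks, ex$tracks)
})

test_that("exhaustive enumeration matches hand-computed optima on forced cases", {
  p <- motion_model_params()
  # a single detection can only be a false alarm
  one <- data.frame(frame = 1L, ax_um = 10, lat_um = 10)
  ex1 <- exhaustive_map(one, p, frame_rate = 50)
  expect_equal(length(ex1$tracks), 0)
  expect_equal(ex1$false_alarms, 1L)

  # 2 frames x 1 close detection each with high p_detect: one track wins;
  # hand-enumerate both candidate partitions with the R reference scorer
  two <- data.frame(frame = 1:2, ax_um = c(500, 510), lat_um = c(500, 500))
  two <- rbind(two, data.frame(frame = 1L, ax_um = c(0, 1000),
                               lat_um = c(0, 1000)))
  cand <- list(list(), list(c(1L, 2L)))
  scores <- vapply(cand, function(tr) {
    ref_log_likelihood(tr, two, p, 50, bbox_area(two)) +
      ref_log_prior(tr, two, p)
  }, numeric(1))
  ex2 <- exhaustive_map(two, p, frame_rate = 50)
  expect_equal(ex2$log_posterior, max(scores), tolerance = 1e-9)
  expect_equal(length(ex2$tracks), which.max(scores) - 1)

  # 2 frames x 2 detections: enumerate all 7 valid partitions by hand
  four <- data.frame(frame = c(1L, 1L, 2L, 2L),
                     ax_um = c(100, 900, 120, 880),
                     lat_um = c(500, 500, 500, 500))
  partitions <- list(
    list(), list(c(1L, 3L)), list(c(1L, 4L)), list(c(2L, 3L)),
    list(c(2L, 4L)), list(c(1L, 3L), c(2L, 4L)),
    list(c(1L, 4L), c(2L, 3L)))
  # keep only gate-respecting partitions, as the enumerator does
  gate_um <- p$max_speed * 1000 / 50 + p$gate_slack
  ok <- vapply(partitions, function(tr) {
    all(vapply(tr, function(t) {
      sqrt(diff(four$ax_um[t])^2 + diff(four$lat_um[t])^2) <= gate_um
    }, logical(1)))
  }, logical(1))
  scores <- vapply(partitions[ok], function(tr) {
    ref_log_likelihood(tr, four, p, 50, bbox_area(four)) +
      ref_log_prior(tr, four, p)
  }, numeric(1))
  ex3 <- exhaustive_map(four, p, frame_rate = 50)
  expect_equal(ex3$log_posterior, max(scores), tolerance = 1e-9)
  expect_error(
    exhaustive_map(data.frame(frame = rep(1:4, each = 3),
                              ax_um = runif(12), lat_um = runif(12)), p,
                   frame_rate = 50), "refused")
})

test_that("the sampler matches the exhaustive oracle on random tiny instances", {
  p <- motion_model_params()
  set.seed(77)
  for (r in 1:25) {
    nf <- sample(2:4, 1)
    n <- sample(4:10, 1)
    fr <- sort(sample(rep(seq_len(nf), length.out = n)))
    dd <- data.frame(frame = fr, ax_um = runif(n, 0, 400),
                     lat_um = runif(n, 0, 400))
    # plant a coherent mover in half the instances
    if (r %% 2 == 0) {
      mv <- which(!duplicated(dd$frame))
      dd$ax_um[mv] <- 50 + 30 * (dd$frame[mv] - 1)
      dd$lat_um[mv] <- 200 + 10 * (dd$frame[mv] - 1)
    }
    ex <- exhaustive_map(dd, p, frame_rate = 50)
    mc <- run_mcmcda(dd, p, n_iterations = 30000, frame_rate = 50,
                     seed = r, debug = TRUE)
    expect_equal(mc$log_posterior, ex$log_posterior, tolerance = 1e-9)
    expect_identical(mc$tracks, ex$tracks)
  }
})

test_that("the chain maintains a valid partition and never links within a frame", {
  p <- motion_model_params()
  set.seed(5)
  dd <- data.frame(frame = rep(1:8, each = 4),
                   ax_um = runif(32, 0, 300), lat_um = runif(32, 0, 300))
  # debug = TRUE validates the partition after every accepted move in C++
  mc <- run_mcmcda(dd, p, n_iterations = 50000, frame_rate = 50, seed = 6,
                   debug = TRUE)
  idx <- unlist(mc$tracks)
  expect_equal(anyDuplicated(idx), 0)
  expect_setequal(c(idx, mc$false_alarms), seq_len(32))
  for (tr in mc$tracks) {
    expect_true(all(diff(dd$frame[tr]) >= 1))
  }
})

test_that("kinematics are gap-aware and recover phantom speeds", {
  det <- data.frame(frame = c(1L, 2L, 4L),
                    ax_um = c(0, 0, 0) + 100,
                    lat_um = c(0, 20, 60) + 100)
  tab <- list(tracks = list(c(1L, 2L, 3L)), false_alarms = integer(0),
              detections = det, log_posterior = 0, frame_rate = 50,
              area = 1, params = NULL)
  class(tab) <- "association"
  kin <- tracks_to_kinematics(tab, frame_rate = 50)
  # 20 um in 1 frame at 50 Hz -> 1 mm/s; 40 um over a 2-frame gap -> 1 mm/s
  expect_equal(kin$steps$speed_mm_s, c(1, 1))
  expect_equal(kin$steps$direction, c(0, 0)) # +lateral axis
  expect_equal(kin$tracks$mean_speed, 1)

  ph <- straight_vessel_phantom(duration = 2, seed = 31)
  det2 <- detect_bubbles(ph$stack, threshold = 0.1, min_pixels = 2)
  mc <- run_mcmcda(det2, motion_model_params(), seed = 3)
  kin2 <- tracks_to_kinematics(mc)
  st <- kin2$steps
  st$vessel <- vapply(st$ax0_um, function(a) which.min(abs(ph$rows - a)),
                      integer(1))
  per_vessel <- vapply(split(st$speed_mm_s, st$vessel), mean, numeric(1))
  truth_speed <- ph$speeds[as.integer(names(per_vessel))]
  expect_true(all(abs(per_vessel - truth_speed) / truth_speed < 0.05))
  # track lengths in the plausible regime: multiple detections, gate-legal
  lens <- vapply(mc$tracks, length, integer(1))
  expect_true(all(lens >= 2))
})
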