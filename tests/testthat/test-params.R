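test_that("rBV is the covered fraction of the region", {
  region <- matrix(TRUE, 10, 10)
  none <- matrix(FALSE, 10, 10)
  expect_equal(compute_rbv(none, region), 0)
  expect_equal(compute_rbv(region, region), 1)
  tm <- matrix(FALSE, 10, 10); tm[1:5, 1:5] <- TRUE
  expect_equal(compute_rbv(tm, region), 0.25)
  expect_error(compute_rbv(tm, none), "empty")
})

test_that("distance maps match the brute-force oracle and the metric", {
  tm <- matrix(FALSE, 9, 9); tm[5, 5] <- TRUE
  dm <- distance_map(tm, pixel_size = 5)
  expect_equal(dm[5, 5], 0)
  expect_equal(dm[5, 6], 5)        # 4-neighbour
  expect_equal(dm[4, 4], 5 * sqrt(2)) # diagonal
  set.seed(14)
  for (i in 1:10) {
    t2 <- matrix(runif(400) < 0.05, 20, 20)
    if (!any(t2)) t2[7, 7] <- TRUE
    expect_equal(distance_map(t2, 5), ref_distance_map(t2, 5),
                 tolerance = 1e-9)
  }
  expect_error(distance_map(matrix(FALSE, 5, 5), 5), "no vessels")
})

test_that("adding vessels never increases any distance", {
  set.seed(3)
  t1 <- matrix(runif(900) < 0.03, 30, 30)
  if (!any(t1)) t1[4, 9] <- TRUE
  t2 <- t1
  t2[sample(which(!t1), 5)] <- TRUE
  expect_true(all(distance_map(t2, 5) <= distance_map(t1, 5) + 1e-9))
})

test_that("distance and velocity statistics are the population summaries", {
  region <- matrix(TRUE, 3, 1)
  dm <- matrix(c(0, 5, 10), 3, 1)
  st <- distance_stats(dm, region)
  expect_equal(unname(st), c(5, mean((c(0, 5, 10) - 5)^2), 10, 5))
  zero <- matrix(0, 3, 1)
  expect_equal(unname(distance_stats(zero, region)), c(0, 0, 0, 0))

  tm <- matrix(TRUE, 2, 2)
  vm <- matrix(0.7, 2, 2)
  vs <- velocity_stats(vm, tm, tm)
  expect_equal(unname(vs), c(0.7, 0, 0.7, 0.7))
  vm2 <- matrix(c(0.4, 1.0, 0.4, 1.0), 2, 2)
  vs2 <- velocity_stats(vm2, tm, tm)
  expect_equal(vs2[["mean"]], 0.7)
  expect_gte(vs2[["maximum"]], vs2[["median"]])
  expect_warning(v0 <- velocity_stats(vm, matrix(FALSE, 2, 2), tm),
                 "undefined")
  expect_true(all(is.na(v0)))
})

test_that("velocity stratification splits the track pixels exactly", {
  tm <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2, 3)
  vm <- matrix(NA_real_, 2, 3)
  vm[tm] <- c(0.4, 1.0, 0.5, 0.7)
  maps <- manual_maps(tm, velocity_map = vm)
  s <- stratify_by_velocity(maps, threshold = 0.7)
  expect_equal(vm[s$low], c(0.4, 0.5))
  expect_equal(vm[s$high], c(1.0, 0.7)) # >= threshold goes high
  expect_true(all((s$low | s$high) == tm))
  expect_equal(sum(s$low & s$high), 0)
  all_slow <- manual_maps(tm, velocity_map = ifelse(tm, 0.5, NA))
  s2 <- stratify_by_velocity(all_slow, 0.7)
  expect_equal(sum(s2$high), 0)
  # all-slow phantom: stratified stats on the low map equal unstratified
  expect_equal(distance_map(s2$low, 5), distance_map(tm, 5))
  expect_equal(cohort_velocity_threshold(c(0.6, 0.8)), 0.7)
})

test_that("direction entropy reproduces closed forms and its bounds", {
  # all directions identical -> 0 bits
  tm <- matrix(TRUE, 10, 10)
  d0 <- matrix(0.3, 10, 10)
  m0 <- manual_maps(tm, direction_map = d0, rim_thickness = 5)
  expect_equal(direction_entropy(m0, m0$roi_mask, 25, 8), 0)
  # equal occupancy of the 8 angular bins in every 5x5 tile -> 3 bits;
  # 24 track pixels per tile (3 per bin), the 25th is off-track
  centres <- -pi + (seq_len(8) - 0.5) * (2 * pi / 8)
  tmu <- matrix(TRUE, 10, 10)
  du <- matrix(NA_real_, 10, 10)
  d2 <- matrix(NA_real_, 10, 10)
  for (r0 in c(1, 6)) {
    for (c0 in c(1, 6)) {
      cells <- as.matrix(expand.grid(r = r0:(r0 + 4), c = c0:(c0 + 4)))
      tmu[cells[25, 1], cells[25, 2]] <- FALSE
      du[cells[1:24, ]] <- rep(centres, 3)
      d2[cells[1:24, ]] <- rep(centres[c(2, 6)], 12)
    }
  }
  mu <- manual_maps(tmu, direction_map = du, rim_thickness = 5)
  expect_equal(direction_entropy(mu, mu$roi_mask, 25, 8), 3)
  # two equally occupied bins per tile -> 1 bit
  m2 <- manual_maps(tmu, direction_map = d2, rim_thickness = 5)
  expect_equal(direction_entropy(m2, m2$roi_mask, 25, 8), 1)
  # bounds on random data
  set.seed(8)
  dr <- matrix(runif(100, -pi, pi), 10, 10)
  tr <- matrix(runif(100) < 0.5, 10, 10)
  mr <- manual_maps(tr, direction_map = ifelse(tr, dr, NA),
                    rim_thickness = 5)
  er <- direction_entropy(mr, mr$roi_mask, 25, 8)
  expect_gte(er, 0)
  expect_lte(er, 3)
  # empty: flagged undefined
  me <- manual_maps(matrix(FALSE, 10, 10), rim_thickness = 5)
  expect_warning(ee <- direction_entropy(me, me$roi_mask, 25, 8),
                 "undefined")
  expect_true(is.na(ee))
})

test_that("designed inter-vessel spacing is recovered by the distance maximum", {
  # two straight vessels 400 um apart on a 5 um grid: the largest distance
  # to the closest vessel inside the strip between them is ~half the
  # spacing
  tm <- matrix(FALSE, 120, 40)
  tm[20, ] <- TRUE; tm[100, ] <- TRUE
  dm <- distance_map(tm, 5)
  strip <- matrix(FALSE, 120, 40); strip[20:100, ] <- TRUE
  st <- distance_stats(dm, strip)
  expect_equal(st[["maximum"]], 200, tolerance = 0.05)
})

test_that("vascular_params assembles a coherent one-row summary", {
  ph <- straight_vessel_phantom(duration = 2, seed = 51)
  det <- detect_bubbles(ph$stack, threshold = 0.1, min_pixels = 2)
  mc <- run_mcmcda(det, motion_model_params(), seed = 7)
  maps <- rasterize_tracks(tracks_to_kinematics(mc), pixel_size = 5,
                           bounds = list(ax = c(0, ph$region[1]),
                                         lat = c(0, ph$region[2])))
  pv <- vascular_params(maps, region = "whole")
  expect_equal(nrow(pv), 1)
  expect_gt(pv$rbv, 0); expect_lt(pv$rbv, 1)
  expect_true(pv$dist_max >= pv$dist_median)
  expect_gte(pv$vel_max, pv$vel_median)
  expect_gte(pv$direction_entropy, 0)
  # horizontal flow only: velocities straddle 0.7, both strata present
  expect_false(is.na(pv$distlow_mean))
  expect_false(is.na(pv$disthigh_mean))
})
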