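# Shared fixtures: small phantoms built in code at test time.

# Ten straight horizontal vessels at known speeds, designed so every bubble
# blob stays fully inside the frame (no edge clipping of centroids).
straight_vessel_phantom <- function(duration = 4, bubble_rate = 12,
                                    noise_sigma = 0, background = 0,
                                    seed = 2) {
  region <- c(1110, 1400)
  rows <- seq(57.5, by = 110, length.out = 10) # 5 um pixel centres
  speeds <- seq(0.3, 1.2, length.out = 10)
  segs <- lapply(1:10, function(i) {
    vessel_segment(c(rows[i], 100), c(rows[i], 1300), radius = 20,
                   flow_speed = speeds[i])
  })
  truth <- simulate_bubbles(segs, duration, frame_rate = 50,
                            bubble_rate = bubble_rate,
                            min_separation = 400, seed = seed)
  stack <- render_frames(truth, region, pixel_spacing = c(11.6, 11.6),
                         background_amplitude = background,
                         noise_sigma = noise_sigma, seed = seed + 1)
  list(truth = truth, stack = stack, rows = rows, speeds = speeds,
       region = region)
}

# map each detection to the ground-truth bubble nearest in its frame
match_detections_to_truth <- function(det, truth) {
  D <- det$detections
  tb <- truth$bubbles
  D$bid <- vapply(seq_len(nrow(D)), function(i) {
    cand <- which(tb$frame == D$frame[i])
    if (!length(cand)) return(NA_integer_)
    as.integer(tb$bubble[cand[which.min(
      (tb$ax_um[cand] - D$ax_um[i])^2 + (tb$lat_um[cand] - D$lat_um[i])^2)]])
  }, integer(1))
  D$truth_err <- vapply(seq_len(nrow(D)), function(i) {
    cand <- which(tb$frame == D$frame[i])
    if (!length(cand)) return(Inf)
    sqrt(min((tb$ax_um[cand] - D$ax_um[i])^2 +
               (tb$lat_um[cand] - D$lat_um[i])^2))
  }, numeric(1))
  D
}

# detection-to-detection links of an association as a 2-column matrix
association_links <- function(assoc) {
  out <- lapply(assoc$tracks, function(t) cbind(t[-length(t)], t[-1]))
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# superres_maps built directly from given maps (bypasses rasterization),
# for parameter-layer unit tests
manual_maps <- function(track_map, velocity_map = NULL, direction_map = NULL,
                        count_map = NULL, roi_mask = NULL, pixel_size = 5,
                        rim_thickness = 500) {
  nr <- nrow(track_map); nc <- ncol(track_map)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nr, nc)
  if (is.null(velocity_map)) {
    velocity_map <- matrix(NA_real_, nr, nc)
    velocity_map[track_map] <- 1
  }
  if (is.null(direction_map)) {
    direction_map <- matrix(NA_real_, nr, nc)
    direction_map[track_map] <- 0
  }
  if (is.null(count_map)) count_map <- track_map * 1L
  rc <- suppressWarnings(split_rim_core(roi_mask, pixel_size, rim_thickness))
  structure(
    list(pixel_size = pixel_size, origin = c(0, 0), track_map = track_map,
         velocity_map = velocity_map, direction_map = direction_map,
         count_map = count_map, roi_mask = roi_mask, rim_mask = rc$rim,
         core_mask = rc$core),
    class = "superres_maps")
}
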