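#' Construct a vessel segment
#'
#' A straight vessel segment carrying plug flow at a constant speed, used by
#' the synthetic phantom. Endpoints are in micrometres (axial, lateral); the
#' flow direction is the unit vector from `p1` to `p2`.
#'
#' @param p1,p2 numeric length-2, segment endpoints in micrometres
#'   (axial, lateral). Must be distinct.
#' @param radius vessel radius in micrometres (> 0). Tumour capillaries run
#'   roughly 5-80 um in diameter, which bounds the defaults used elsewhere.
#' @param flow_speed flow speed in mm/s (>= 0).
#' @return an object of class `vessel_segment`.
#' @export
vessel_segment <- function(p1, p2, radius, flow_speed) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L) {
    stopf("endpoints must be length-2 (axial, lateral)")
  }
  if (all(p1 == p2)) stopf("segment endpoints must be distinct")
  if (!is.finite(radius) || radius <= 0) stopf("radius must be > 0")
  if (!is.finite(flow_speed) || flow_speed < 0) stopf("flow_speed must be >= 0")
  d <- p2 - p1
  structure(
    list(p1 = p1, p2 = p2, radius = radius, flow_speed = flow_speed,
         direction = d / sqrt(sum(d^2)), length = sqrt(sum(d^2))),
    class = "vessel_segment"
  )
}

#' Generate a random vessel network
#'
#' Draws straight vessel segments uniformly inside a rectangular region.
#' Radii span the small-vessel regime of tumour microvasculature by default.
#'
#' @param region_size numeric length-2, region extent in micrometres
#'   (axial, lateral).
#' @param n_segments number of segments (>= 1).
#' @param radius_range,speed_range numeric length-2 intervals for radii (um)
#'   and flow speeds (mm/s).
#' @param min_length minimum segment length in micrometres.
#' @param seed integer seed; identical inputs give identical networks.
#' @return list of [vessel_segment()] objects.
#' @export
generate_vessel_network <- function(region_size, n_segments,
                                    radius_range = c(5, 40),
                                    speed_range = c(0.3, 1.2),
                                    min_length = 0.3 * min(region_size),
                                    seed = 1L) {
  region_size <- as.numeric(region_size)
  if (length(region_size) != 2L || any(!is.finite(region_size)) ||
      any(region_size <= 0)) {
    stopf("region_size must be two positive lengths (um)")
  }
  if (n_segments < 1) stopf("n_segments must be >= 1")
  ok_range <- function(r) length(r) == 2L && all(is.finite(r)) &&
    all(r > 0) && r[1] <= r[2]
  if (!ok_range(radius_range)) stopf("invalid radius_range")
  if (!(ok_range(speed_range) || all(speed_range == 0))) {
    stopf("invalid speed_range")
  }
  set.seed(seed)
  segs <- vector("list", n_segments)
  for (i in seq_len(n_segments)) {
    repeat {
      p1 <- runif(2) * region_size
      p2 <- runif(2) * region_size
      if (sqrt(sum((p2 - p1)^2)) >= min_length) break
    }
    segs[[i]] <- vessel_segment(
      p1, p2,
      radius = runif(1, radius_range[1], radius_range[2]),
      flow_speed = runif(1, speed_range[1], speed_range[2])
    )
  }
  segs
}

#' Simulate microbubble transits through a vessel network
#'
#' Bubbles enter segments at Poisson times, advance along the segment axis at
#' the segment's flow speed and leave at the far end. An optional
#' destruction event removes every circulating bubble and suppresses new
#' arrivals for a dead window; afterwards arrivals resume, optionally ramped
#' up with time constant `replenish_tau` to emulate reflow through the
#' feeding vasculature (which makes replenishment kinetics slower than the
#' in-plane bubble speed).
#'
#' @param segments list of [vessel_segment()].
#' @param duration sequence duration in seconds.
#' @param frame_rate frames per second (default 50).
#' @param bubble_rate expected bubble arrivals per second over the whole
#'   network.
#' @param destruction_frame optional 1-based frame index of a destructive
#'   pulse.
#' @param dead_window number of frames after `destruction_frame` in which no
#'   bubble may appear.
#' @param replenish_tau reflow ramp time constant in seconds (0 = immediate
#'   full-rate reflow).
#' @param min_separation minimum along-vessel spacing (um) between bubbles
#'   entering the same segment; keeps blobs resolvable.
#' @param lateral_jitter_sd across-vessel position s.d. in um (0 = bubbles on
#'   the centreline).
#' @param seed integer seed.
#' @return an object of class `phantom_truth`: list with `segments`,
#'   `bubbles` (data.frame: bubble, frame, t, ax_um, lat_um, segment),
#'   `n_frames`, `frame_rate`, `destruction_frame`, `dead_window`.
#' @export
simulate_bubbles <- function(segments, duration, frame_rate = 50,
                             bubble_rate = 5, destruction_frame = NULL,
                             dead_window = 0, replenish_tau = 0,
                             min_separation = 200, lateral_jitter_sd = 0,
                             seed = 1L) {
  if (!is.finite(duration) || duration <= 0) stopf("duration must be > 0")
  if (bubble_rate < 0) stopf("bubble_rate must be >= 0")
  set.seed(seed)
  n_frames <- max(2L, as.integer(round(duration * frame_rate)))
  t_dead_end <- if (!is.null(destruction_frame)) {
    (destruction_frame - 1 + dead_window) / frame_rate
  } else -Inf
  t_destr <- if (!is.null(destruction_frame)) {
    (destruction_frame - 1) / frame_rate
  } else Inf

  # Poisson arrivals, thinned during the dead window and the reflow ramp.
  arrivals <- numeric(0)
  if (bubble_rate > 0) {
    t <- 0
    repeat {
      t <- t + rexp(1, bubble_rate)
      if (t >= duration) break
      keep <- TRUE
      if (t >= t_destr && t < t_dead_end) keep <- FALSE
      if (keep && t >= t_dead_end && replenish_tau > 0) {
        keep <- runif(1) < (1 - exp(-(t - t_dead_end) / replenish_tau))
      }
      if (keep) arrivals <- c(arrivals, t)
    }
  }

  rows <- list()
  entry_log <- lapply(segments, function(s) numeric(0)) # entry times per seg
  bubble_id <- 0L
  for (t0 in arrivals) {
    si <- sample.int(length(segments), 1L)
    seg <- segments[[si]]
    speed_ums <- seg$flow_speed * 1000 # um/s
    # spacing guard: previous bubble on this segment must have cleared
    # min_separation um before a new one enters
    prev <- entry_log[[si]]
    if (length(prev) > 0 && speed_ums > 0) {
      if ((t0 - max(prev)) * speed_ums < min_separation) next
    }
    entry_log[[si]] <- c(entry_log[[si]], t0)
    bubble_id <- bubble_id + 1L
    t_exit <- if (speed_ums > 0) t0 + seg$length / speed_ums else duration
    off <- if (lateral_jitter_sd > 0) {
      rnorm(1, 0, lateral_jitter_sd) * c(-seg$direction[2], seg$direction[1])
    } else c(0, 0)
    f0 <- as.integer(ceiling(t0 * frame_rate + 1))
    f1 <- as.integer(min(n_frames, floor(t_exit * frame_rate + 1)))
    if (f0 > f1) next
    fr <- f0:f1
    tt <- (fr - 1) / frame_rate
    alive <- rep(TRUE, length(fr))
    if (!is.null(destruction_frame)) {
      alive <- fr < destruction_frame | tt >= t_dead_end
      # bubbles present at the destructive pulse are destroyed outright
      if (t0 < t_destr) alive <- alive & (fr < destruction_frame)
    }
    if (!any(alive)) next
    fr <- fr[alive]; tt <- tt[alive]
    pos <- outer(rep(1, length(tt)), seg$p1 + off) +
      outer((tt - t0) * speed_ums, rep(1, 2)) *
        outer(rep(1, length(tt)), seg$direction)
    rows[[length(rows) + 1L]] <- data.frame(
      bubble = bubble_id, frame = fr, t = tt,
      ax_um = pos[, 1], lat_um = pos[, 2], segment = si
    )
  }
  bubbles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bubble = integer(0), frame = integer(0), t = numeric(0),
               ax_um = numeric(0), lat_um = numeric(0), segment = integer(0))
  structure(
    list(segments = segments, bubbles = bubbles, n_frames = n_frames,
         frame_rate = frame_rate, destruction_frame = destruction_frame,
         dead_window = dead_window),
    class = "phantom_truth"
  )
}

#' Construct a frame stack
#'
#' @param frames 3D non-negative array (axial x lateral x time).
#' @param frame_rate frames per second (> 0).
#' @param pixel_spacing length-2 (axial, lateral) micrometres per pixel.
#' @param destruction_frame optional 1-based destructive-pulse frame index.
#' @param excluded optional logical per frame (frames unusable downstream).
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, pixel_spacing,
                        destruction_frame = NULL, excluded = NULL) {
  if (length(dim(frames)) != 3L) stopf("frames must be a 3D array")
  if (dim(frames)[3] < 2L) stopf("need at least 2 frames")
  if (!is.finite(frame_rate) || frame_rate <= 0) {
    stopf("frame_rate must be > 0")
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0)) {
    stopf("pixel_spacing must be two positive lengths (um)")
  }
  if (min(frames) < 0) stopf("frame intensities must be non-negative")
  if (is.null(excluded)) excluded <- rep(FALSE, dim(frames)[3])
  structure(
    list(frames = frames, frame_rate = frame_rate,
         pixel_spacing = pixel_spacing,
         destruction_frame = destruction_frame, excluded = excluded),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "frame_stack: %d x %d pixels, %d frames @ %g Hz, %g x %g um/px\n",
    d[1], d[2], d[3], x$frame_rate, x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

# speckle: low-pass filtered white noise, strictly positive, mean ~ amplitude
speckle_background <- function(nr, nc, amplitude, corr_px = 3) {
  if (amplitude <= 0) return(matrix(0, nr, nc))
  z <- matrix(rnorm(nr * nc), nr, nc)
  k <- 2 * ceiling(2 * corr_px) + 1
  g <- dnorm(seq(-floor(k / 2), floor(k / 2)), sd = corr_px)
  g <- g / sum(g)
  z <- apply(z, 2, function(col) as.numeric(stats::filter(col, g, sides = 2,
                                                          circular = TRUE)))
  z <- t(apply(z, 1, function(row) as.numeric(stats::filter(row, g, sides = 2,
                                                            circular = TRUE))))
  amplitude * (1 + z / max(abs(z)))
}

# bilinear sub-pixel translation by `shift_px` = (d_row, d_col); out-of-range
# samples take the nearest edge value
shift_image <- function(img, shift_px) {
  nr <- nrow(img); nc <- ncol(img)
  r <- seq_len(nr) - shift_px[1]
  c <- seq_len(nc) - shift_px[2]
  r0 <- pmin(pmax(floor(r), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(c), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(c - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE]; b <- img[r1, c0, drop = FALSE]
  d <- img[r0, c1, drop = FALSE]; e <- img[r1, c1, drop = FALSE]
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b +
    (1 - wr) * wc * d + wr * wc * e
}

#' Render a phantom truth into a frame stack
#'
#' Each bubble becomes an anisotropic Gaussian blob centred at its true
#' sub-pixel position, added onto a static speckle background that is shared
#' across frames. The whole frame (tissue and bubbles) is then rigidly
#' shifted by the per-frame motion profile, frames listed in
#' `decorr_frames` receive multiplicative decorrelation noise (emulating
#' out-of-plane corruption during breathing spikes), and white noise is
#' added. Intensities are clipped at zero.
#'
#' Default PSF sigmas correspond to a full width at half maximum of 40 um
#' axially and 90 um laterally, the focal resolution of a 40 MHz preclinical
#' linear array.
#'
#' @param truth a `phantom_truth` from [simulate_bubbles()].
#' @param region_size imaged region in micrometres (axial, lateral).
#' @param psf_sigma Gaussian PSF sigma in um (axial, lateral).
#' @param pixel_spacing um per pixel (axial, lateral).
#' @param bubble_amplitude peak blob intensity.
#' @param background_amplitude mean speckle intensity (0 = no background).
#' @param noise_sigma additive white-noise s.d.
#' @param motion_profile optional n_frames x 2 matrix of rigid displacements
#'   in um (axial, lateral) applied to each frame.
#' @param decorr_frames frames receiving multiplicative decorrelation noise.
#' @param decorr_sd s.d. of the multiplicative noise on those frames.
#' @param seed integer seed (drives speckle and noise).
#' @return a [frame_stack()]; the applied `motion_profile` and the truth are
#'   attached as attributes `motion_profile` and `truth`.
#' @export
render_frames <- function(truth, region_size,
                          psf_sigma = c(40, 90) / (2 * sqrt(2 * log(2))),
                          pixel_spacing = c(11.6, 11.6),
                          bubble_amplitude = 1,
                          background_amplitude = 0, noise_sigma = 0,
                          motion_profile = NULL,
                          decorr_frames = integer(0), decorr_sd = 0.5,
                          seed = 1L) {
  if (any(psf_sigma <= 0)) stopf("psf_sigma must be > 0")
  if (any(pixel_spacing <= 0)) stopf("pixel_spacing must be > 0")
  set.seed(seed)
  nr <- as.integer(ceiling(region_size[1] / pixel_spacing[1]))
  nc <- as.integer(ceiling(region_size[2] / pixel_spacing[2]))
  nt <- truth$n_frames
  if (is.null(motion_profile)) motion_profile <- matrix(0, nt, 2)
  if (nrow(motion_profile) != nt) {
    stopf("motion_profile must have one row per frame")
  }
  bg <- speckle_background(nr, nc, background_amplitude)
  frames <- array(0, dim = c(nr, nc, nt))
  ax_px <- (seq_len(nr) - 1) * pixel_spacing[1]
  lat_px <- (seq_len(nc) - 1) * pixel_spacing[2]
  halfw <- ceiling(4 * psf_sigma / pixel_spacing)
  bub <- truth$bubbles
  by_frame <- if (nrow(bub)) split(seq_len(nrow(bub)), bub$frame) else list()
  for (f in seq_len(nt)) {
    img <- bg
    idx <- by_frame[[as.character(f)]]
    for (i in idx) {
      a <- bub$ax_um[i]; l <- bub$lat_um[i]
      r0 <- max(1L, floor(a / pixel_spacing[1]) - halfw[1])
      r1 <- min(nr, floor(a / pixel_spacing[1]) + halfw[1] + 1)
      c0 <- max(1L, floor(l / pixel_spacing[2]) - halfw[2])
      c1 <- min(nc, floor(l / pixel_spacing[2]) + halfw[2] + 1)
      if (r0 > r1 || c0 > c1) next # fully out of field: clipped silently
      ga <- exp(-(ax_px[r0:r1] - a)^2 / (2 * psf_sigma[1]^2))
      gl <- exp(-(lat_px[c0:c1] - l)^2 / (2 * psf_sigma[2]^2))
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
        bubble_amplitude * outer(ga, gl)
    }
    if (any(motion_profile[f, ] != 0)) {
      img <- shift_image(img, motion_profile[f, ] / pixel_spacing)
    }
    if (f %in% decorr_frames && decorr_sd > 0) {
      img <- img * pmax(0, 1 + matrix(rnorm(nr * nc, 0, decorr_sd), nr, nc))
    }
    if (noise_sigma > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
    }
    frames[, , f] <- pmax(img, 0)
  }
  out <- frame_stack(frames, truth$frame_rate, pixel_spacing,
                     destruction_frame = truth$destruction_frame)
  attr(out, "motion_profile") <- motion_profile
  attr(out, "truth") <- truth
  out
}

#' Breathing-like motion profile
#'
#' Small jitter on every frame plus large displacement spikes on selected
#' frames, the pattern that motivates frame exclusion.
#'
#' @param n_frames number of frames.
#' @param spike_frames frame indices carrying large displacements.
#' @param spike_amplitude spike magnitude in um.
#' @param jitter_sd baseline jitter s.d. in um.
#' @param seed integer seed.
#' @return n_frames x 2 matrix of displacements (um); frame 1 is the
#'   reference and stays at zero.
#' @export
make_motion_profile <- function(n_frames, spike_frames = integer(0),
                                spike_amplitude = 80, jitter_sd = 0,
                                seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n_frames * 2, 0, jitter_sd), n_frames, 2)
  for (f in spike_frames) {
    th <- runif(1, 0, 2 * pi)
    m[f, ] <- spike_amplitude * c(cos(th), sin(th))
  }
  m[1, ] <- 0
  m
}
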