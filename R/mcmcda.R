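#' Motion-model and association-prior parameters
#'
#' Parameters of the constant-velocity motion model and of the association
#' prior used by the tracker: Poisson intensities for track births and false
#' alarms, a binomial detection/miss probability and a geometric track
#' termination probability, plus the Kalman noise scales. The candidate-link
#' gate admits a link only when the implied speed does not exceed
#' `max_speed` (plus slack) and the frame gap does not exceed
#' `max_missed_frames + 1`.
#'
#' @param process_noise_sigma white-acceleration process noise, um per
#'   frame^(3/2) (default 2).
#' @param measurement_noise_sigma localization noise s.d., um (default 5).
#' @param max_speed gating speed, mm/s (default 5; an order of magnitude
#'   above typical tumour capillary flow).
#' @param p_detect per-frame detection probability of an existing bubble.
#' @param false_alarm_rate expected false alarms per frame.
#' @param birth_rate expected new tracks per frame.
#' @param p_terminate per-frame track termination probability.
#' @param max_missed_frames maximum consecutive missed detections bridged by
#'   a track (default 2).
#' @param init_velocity_sigma diffuse initial velocity s.d. in um/frame
#'   (default: `max_speed` expressed in um/frame at 50 Hz).
#' @param gate_slack additive gate slack in um (default 10).
#' @return object of class `motion_model_params`.
#' @export
motion_model_params <- function(process_noise_sigma = 2,
                                measurement_noise_sigma = 5,
                                max_speed = 5,
                                p_detect = 0.9,
                                false_alarm_rate = 1,
                                birth_rate = 0.5,
                                p_terminate = 0.1,
                                max_missed_frames = 2L,
                                init_velocity_sigma = NULL,
                                gate_slack = 10) {
  chk_prob <- function(p, nm) {
    if (!is.finite(p) || p <= 0 || p >= 1) stopf("%s must be in (0,1)", nm)
  }
  chk_prob(p_detect, "p_detect")
  chk_prob(p_terminate, "p_terminate")
  if (process_noise_sigma <= 0 || measurement_noise_sigma <= 0) {
    stopf("noise sigmas must be > 0")
  }
  if (false_alarm_rate < 0 || birth_rate < 0) stopf("rates must be >= 0")
  if (max_speed <= 0) stopf("max_speed must be > 0")
  structure(
    list(process_noise_sigma = process_noise_sigma,
         measurement_noise_sigma = measurement_noise_sigma,
         max_speed = max_speed, p_detect = p_detect,
         false_alarm_rate = false_alarm_rate, birth_rate = birth_rate,
         p_terminate = p_terminate,
         max_missed_frames = as.integer(max_missed_frames),
         init_velocity_sigma = init_velocity_sigma,
         gate_slack = gate_slack),
    class = "motion_model_params"
  )
}

# detection table + FOV area from a detection_set or a plain data.frame
.det_table <- function(detections) {
  if (inherits(detections, "detection_set")) {
    area <- sum(detections$roi_mask) * prod(detections$pixel_spacing)
    list(det = detections$detections, area = max(area, 1),
         frame_rate = detections$frame_rate,
         n_frames = detections$n_frames)
  } else {
    d <- as.data.frame(detections)
    stopifnot(all(c("frame", "ax_um", "lat_um") %in% names(d)))
    span <- function(v) if (length(v)) max(diff(range(v)), 1) else 1
    list(det = d, area = span(d$ax_um) * span(d$lat_um),
         frame_rate = NULL, n_frames = if (nrow(d)) max(d$frame) else 0L)
  }
}

# convert user parameters to the per-frame um units used by the C++ core
.cpp_params <- function(params, frame_rate, area) {
  stopifnot(inherits(params, "motion_model_params"))
  um_per_frame <- params$max_speed * 1000 / frame_rate
  v0 <- params$init_velocity_sigma %||% um_per_frame
  list(process_noise_sigma = params$process_noise_sigma,
       measurement_noise_sigma = params$measurement_noise_sigma,
       init_velocity_sigma = v0,
       gate_speed = um_per_frame,
       gate_slack = params$gate_slack,
       max_gap = params$max_missed_frames + 1L,
       p_detect = params$p_detect,
       p_terminate = params$p_terminate,
       birth_rate = params$birth_rate,
       false_alarm_rate = params$false_alarm_rate,
       area = area)
}

.as_association <- function(tracks, tab, params, frame_rate, log_posterior) {
  in_tracks <- unlist(tracks)
  structure(
    list(tracks = tracks,
         false_alarms = setdiff(seq_len(nrow(tab$det)), in_tracks),
         detections = tab$det, log_posterior = log_posterior,
         frame_rate = frame_rate, area = tab$area, params = params),
    class = "association"
  )
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf(
    "association: %d tracks, %d false alarms, log posterior %.3f\n",
    length(x$tracks), length(x$false_alarms), x$log_posterior))
  invisible(x)
}

# validate that `tracks` (list of detection row indices) is a partition
.check_partition <- function(tracks, det) {
  idx <- unlist(tracks)
  if (anyDuplicated(idx)) stopf("a detection appears in two tracks")
  if (length(idx) && (min(idx) < 1 || max(idx) > nrow(det))) {
    stopf("track indices out of range")
  }
  for (tr in tracks) {
    if (length(tr) < 2) stopf("tracks need >= 2 detections")
    f <- det$frame[tr]
    if (any(diff(f) < 1)) stopf("track frames must strictly increase")
  }
  invisible(TRUE)
}

#' Association log-likelihood
#'
#' Log-likelihood of the measured positions under a given association:
#' for each track, each detection is scored against the constant-velocity
#' Kalman prediction from the preceding detections (innovation likelihood,
#' with a diffuse velocity prior at track birth); track births and false
#' alarms are uniform over the field of view. Association-independent
#' constants are dropped.
#'
#' @param tracks list of integer vectors of detection row indices, each in
#'   strictly increasing frame order.
#' @param detections a `detection_set` or a data.frame with columns
#'   `frame`, `ax_um`, `lat_um`.
#' @param params a [motion_model_params()].
#' @param frame_rate Hz (taken from the `detection_set` when omitted).
#' @return scalar log score.
#' @export
association_log_likelihood <- function(tracks, detections, params,
                                       frame_rate = NULL) {
  tab <- .det_table(detections)
  frame_rate <- frame_rate %||% tab$frame_rate
  .check_partition(tracks, tab$det)
  assoc_loglik_cpp(as.integer(tab$det$frame), tab$det$ax_um, tab$det$lat_um,
                   lapply(tracks, as.integer),
                   .cpp_params(params, frame_rate, tab$area))
}

#' Association log-prior
#'
#' Log prior probability of an association, combining Poisson birth and
#' false-alarm intensities, binomial detection/miss factors over each
#' track's lifetime, and geometric survival/termination factors.
#' Association-independent constants are dropped.
#'
#' @inheritParams association_log_likelihood
#' @return scalar log score.
#' @export
association_log_prior <- function(tracks, detections, params,
                                  frame_rate = NULL) {
  tab <- .det_table(detections)
  frame_rate <- frame_rate %||% tab$frame_rate
  .check_partition(tracks, tab$det)
  assoc_logprior_cpp(as.integer(tab$det$frame), tab$det$ax_um, tab$det$lat_um,
                     lapply(tracks, as.integer),
                     .cpp_params(params, frame_rate, tab$area))
}

#' Association log-posterior
#' @inheritParams association_log_likelihood
#' @return scalar: log-likelihood plus log-prior.
#' @export
association_log_posterior <- function(tracks, detections, params,
                                      frame_rate = NULL) {
  association_log_likelihood(tracks, detections, params, frame_rate) +
    association_log_prior(tracks, detections, params, frame_rate)
}

#' Track microbubbles by MCMC data association
#'
#' Runs a Metropolis chain over the space of associations (partitions of the
#' detections into tracks and false alarms) targeting the association
#' posterior, using birth/death, extend/reduce, split/merge, track-switch
#' and point-swap moves. Proposals are restricted by the speed/gap gate. The
#' chain starts from the all-false-alarm association and the best (highest
#' posterior) association visited is returned.
#'
#' @param detections a `detection_set` or data.frame (see
#'   [association_log_likelihood()]).
#' @param params a [motion_model_params()].
#' @param n_iterations number of proposed moves (default `2000 *`
#'   number of detections).
#' @param frame_rate Hz (taken from the `detection_set` when omitted).
#' @param seed integer seed; fixed seed gives a fixed result.
#' @param debug validate the partition invariant after every accepted move
#'   (slow; for testing).
#' @return an `association` object.
#' @export
run_mcmcda <- function(detections, params = motion_model_params(),
                       n_iterations = NULL, frame_rate = NULL, seed = 1L,
                       debug = FALSE) {
  tab <- .det_table(detections)
  frame_rate <- frame_rate %||% tab$frame_rate
  if (is.null(frame_rate)) stopf("frame_rate required")
  n <- nrow(tab$det)
  if (n == 0) {
    return(.as_association(list(), tab, params, frame_rate, 0))
  }
  n_iterations <- as.integer(n_iterations %||% (2000L * n))
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  ord <- order(tab$det$frame, tab$det$ax_um, tab$det$lat_um)
  det <- tab$det[ord, , drop = FALSE]
  set.seed(seed)
  res <- run_mcmcda_cpp(as.integer(det$frame), det$ax_um, det$lat_um,
                        .cpp_params(params, frame_rate, tab$area),
                        n_iterations, debug)
  tracks <- lapply(res$tracks, function(tr) ord[tr]) # back to input order
  tracks <- .canonical_tracks(tracks, tab$det)
  out <- .as_association(tracks, tab, params, frame_rate, res$log_posterior)
  attr(out, "initial_log_posterior") <- res$initial_log_posterior
  out
}

# sort tracks by first frame then position for deterministic output
.canonical_tracks <- function(tracks, det) {
  if (!length(tracks)) return(list())
  key <- vapply(tracks, function(tr) {
    sprintf("%09d_%015.6f_%015.6f", det$frame[tr[1]],
            det$ax_um[tr[1]], det$lat_um[tr[1]])
  }, character(1))
  tracks[order(key)]
}

#' Exhaustive maximum a posteriori association (tiny instances)
#'
#' Enumerates every valid partition of the detections into gated tracks and
#' false alarms and returns the argmax of the association posterior. The
#' full combinatorial enumeration is intractable in general, so this is
#' guarded to at most `max_detections` detections; it serves as the ground
#' truth for validating the sampler on small instances.
#'
#' @inheritParams run_mcmcda
#' @param max_detections refusal guard (default 10).
#' @return an `association` object.
#' @export
exhaustive_map <- function(detections, params = motion_model_params(),
                           frame_rate = NULL, max_detections = 10L) {
  tab <- .det_table(detections)
  frame_rate <- frame_rate %||% tab$frame_rate
  if (is.null(frame_rate)) stopf("frame_rate required")
  n <- nrow(tab$det)
  if (n > max_detections) {
    stopf("exhaustive enumeration refused for %d > %d detections",
          n, max_detections)
  }
  if (n == 0) return(.as_association(list(), tab, params, frame_rate, 0))
  ord <- order(tab$det$frame, tab$det$ax_um, tab$det$lat_um)
  det <- tab$det[ord, , drop = FALSE]
  res <- exhaustive_map_cpp(as.integer(det$frame), det$ax_um, det$lat_um,
                            .cpp_params(params, frame_rate, tab$area))
  tracks <- lapply(res$tracks, function(tr) ord[tr])
  tracks <- .canonical_tracks(tracks, tab$det)
  out <- .as_association(tracks, tab, params, frame_rate, res$log_posterior)
  attr(out, "n_evaluated") <- res$n_evaluated
  out
}

#' Per-track kinematics
#'
#' Computes the step velocities of every track: for each consecutive pair of
#' detections the velocity vector is the position difference divided by the
#' elapsed time (frame gap over frame rate), so bridged missed detections
#' are handled correctly. Directions are `atan2(axial, lateral)` of the
#' velocity vector, in (-pi, pi] measured counterclockwise from the +lateral
#' axis.
#'
#' @param assoc an `association`.
#' @param frame_rate Hz (default: stored in the association).
#' @return list with `steps` (data.frame: track, frame_from, frame_to,
#'   ax0_um, lat0_um, ax1_um, lat1_um, v_ax_mm_s, v_lat_mm_s, speed_mm_s,
#'   direction) and `tracks` (data.frame: track, n_detections, mean_speed).
#' @export
tracks_to_kinematics <- function(assoc, frame_rate = NULL) {
  stopifnot(inherits(assoc, "association"))
  frame_rate <- frame_rate %||% assoc$frame_rate
  det <- assoc$detections
  steps <- list()
  for (k in seq_along(assoc$tracks)) {
    tr <- assoc$tracks[[k]]
    f <- det$frame[tr]; a <- det$ax_um[tr]; l <- det$lat_um[tr]
    n <- length(tr)
    dt <- diff(f) / frame_rate                    # seconds, gap-aware
    v_ax <- diff(a) / dt / 1000                   # mm/s
    v_lat <- diff(l) / dt / 1000
    steps[[k]] <- data.frame(
      track = k, frame_from = f[-n], frame_to = f[-1],
      ax0_um = a[-n], lat0_um = l[-n], ax1_um = a[-1], lat1_um = l[-1],
      v_ax_mm_s = v_ax, v_lat_mm_s = v_lat,
      speed_mm_s = sqrt(v_ax^2 + v_lat^2),
      direction = atan2(v_ax, v_lat)
    )
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(track = integer(0), frame_from = integer(0),
               frame_to = integer(0), ax0_um = numeric(0),
               lat0_um = numeric(0), ax1_um = numeric(0),
               lat1_um = numeric(0), v_ax_mm_s = numeric(0),
               v_lat_mm_s = numeric(0), speed_mm_s = numeric(0),
               direction = numeric(0))
  tracks <- if (length(assoc$tracks)) {
    data.frame(
      track = seq_along(assoc$tracks),
      n_detections = vapply(assoc$tracks, length, integer(1)),
      mean_speed = vapply(
        split(steps$speed_mm_s,
              factor(steps$track, levels = seq_along(assoc$tracks))),
        mean, numeric(1))
    )
  } else {
    data.frame(track = integer(0), n_detections = integer(0),
               mean_speed = numeric(0))
  }
  list(steps = steps, tracks = tracks)
}

#' Write tracks to CSV
#' @param assoc an `association`.
#' @param path output CSV path.
#' @param frame_rate Hz (default: stored in the association).
#' @export
write_tracks <- function(assoc, path, frame_rate = NULL) {
  frame_rate <- frame_rate %||% assoc$frame_rate
  det <- assoc$detections
  rows <- list()
  kin <- tracks_to_kinematics(assoc, frame_rate)
  for (k in seq_along(assoc$tracks)) {
    tr <- assoc$tracks[[k]]
    st <- kin$steps[kin$steps$track == k, ]
    n <- length(tr)
    rows[[k]] <- data.frame(
      track_id = k, frame = det$frame[tr],
      ax_um = det$ax_um[tr], lat_um = det$lat_um[tr],
      v_ax_mm_s = c(st$v_ax_mm_s, NA), v_lat_mm_s = c(st$v_lat_mm_s, NA)
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), frame = integer(0), ax_um = numeric(0),
               lat_um = numeric(0), v_ax_mm_s = numeric(0),
               v_lat_mm_s = numeric(0))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
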