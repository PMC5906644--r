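# Independent R reference implementations used as oracles against the
# compiled scoring code. These mirror the model definition (constant
# velocity Kalman innovations; Poisson/binomial/geometric prior) but share
# no code with the package internals.

ref_axis_loglik <- function(y, f, q, r, v0) {
  p <- y[1]; v <- 0
  P <- matrix(c(r^2, 0, 0, v0^2), 2, 2)
  Fm <- matrix(c(1, 0, 1, 1), 2, 2) # column-major: [[1,1],[0,1]]
  Q <- q^2 * matrix(c(1 / 3, 1 / 2, 1 / 2, 1), 2, 2)
  ll <- 0
  for (k in seq_along(y)[-1]) {
    for (s in seq_len(f[k] - f[k - 1])) {
      P <- Fm %*% P %*% t(Fm) + Q
      p <- p + v
    }
    S <- P[1, 1] + r^2
    innov <- y[k] - p
    ll <- ll + dnorm(innov, 0, sqrt(S), log = TRUE)
    K <- P[, 1] / S
    p <- p + K[1] * innov
    v <- v + K[2] * innov
    P <- (diag(2) - K %*% t(c(1, 0))) %*% P
  }
  ll
}

ref_log_likelihood <- function(tracks, det, params, frame_rate, area) {
  upf <- params$max_speed * 1000 / frame_rate
  v0 <- if (is.null(params$init_velocity_sigma)) upf else
    params$init_velocity_sigma
  n_fa <- nrow(det) - length(unlist(tracks))
  ll <- -n_fa * log(area)
  for (tr in tracks) {
    ll <- ll - log(area) +
      ref_axis_loglik(det$ax_um[tr], det$frame[tr],
                      params$process_noise_sigma,
                      params$measurement_noise_sigma, v0) +
      ref_axis_loglik(det$lat_um[tr], det$frame[tr],
                      params$process_noise_sigma,
                      params$measurement_noise_sigma, v0)
  }
  ll
}

ref_log_prior <- function(tracks, det, params) {
  n_fa <- nrow(det) - length(unlist(tracks))
  lp <- n_fa * log(params$false_alarm_rate)
  for (tr in tracks) {
    k <- length(tr)
    span <- det$frame[tr[k]] - det$frame[tr[1]]
    lp <- lp + log(params$birth_rate) + (k - 1) * log(params$p_detect) +
      (span - k + 1) * log(1 - params$p_detect) +
      span * log(1 - params$p_terminate) + log(params$p_terminate)
  }
  lp
}

# brute-force nearest-track-pixel distance map (um)
ref_distance_map <- function(track_map, pixel_size) {
  on <- which(track_map, arr.ind = TRUE)
  nr <- nrow(track_map); nc <- ncol(track_map)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- sqrt(min((on[, 1] - r)^2 + (on[, 2] - c)^2)) * pixel_size
    }
  }
  out
}

# the effective FOV area a plain data.frame of detections implies (bounding
# box, floored at 1 um per side) -- mirrors the documented contract
bbox_area <- function(det) {
  span <- function(v) max(diff(range(v)), 1)
  span(det$ax_um) * span(det$lat_um)
}
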