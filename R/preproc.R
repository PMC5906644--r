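#' Rasterize a region-of-interest polygon
#'
#' Fills a polygon (vertices in micrometres, even-odd rule) onto the pixel
#' grid of a frame stack or an explicit grid. A pixel belongs to the ROI when
#' its centre lies inside the polygon.
#'
#' @param vertices n x 2 matrix or data.frame of polygon vertices
#'   (axial_um, lateral_um).
#' @param dim image dimensions (rows, cols).
#' @param pixel_spacing um per pixel (axial, lateral).
#' @param origin physical coordinates (um) of the centre of pixel (1,1).
#' @return logical matrix mask.
#' @export
rasterize_roi <- function(vertices, dim, pixel_spacing, origin = c(0, 0)) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L) stopf("need >= 3 polygon vertices")
  nr <- dim[1]; nc <- dim[2]
  ax <- origin[1] + (seq_len(nr) - 1) * pixel_spacing[1]
  lat <- origin[2] + (seq_len(nc) - 1) * pixel_spacing[2]
  mask <- matrix(FALSE, nr, nc)
  n <- nrow(v)
  # even-odd scanline test per row of pixel centres
  for (r in seq_len(nr)) {
    y <- ax[r]
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- v[i, 1]; y2 <- v[j, 1]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        xs <- c(xs, v[i, 2] + (y - y1) / (y2 - y1) * (v[j, 2] - v[i, 2]))
      }
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        mask[r, lat >= xs[k] & lat < xs[k + 1]] <- TRUE
      }
    }
  }
  mask
}

#' Read/write an ROI polygon
#'
#' CSV with columns `ax_um, lat_um`, or a JSON array of [ax, lat] pairs.
#' @param path file path (.csv or .json).
#' @param vertices n x 2 matrix (axial_um, lateral_um).
#' @return `read_roi_polygon`: an n x 2 matrix.
#' @export
read_roi_polygon <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- jsonlite::fromJSON(path)
    v <- matrix(as.numeric(unlist(v)), ncol = 2, byrow = !is.matrix(v))
  } else {
    d <- read.csv(path)
    v <- cbind(d$ax_um, d$lat_um)
  }
  colnames(v) <- c("ax_um", "lat_um")
  v
}

#' @rdname read_roi_polygon
#' @export
write_roi_polygon <- function(vertices, path) {
  d <- data.frame(ax_um = vertices[, 1], lat_um = vertices[, 2])
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# upsampled cross-correlation peak between two equally sized images, via a
# coarse FFT correlation followed by a matrix-multiply inverse DFT evaluated
# on a fine grid around the coarse peak (Fourier upsampling)
xcorr_peak <- function(ref, img, upsample) {
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- fft(ref - mean(ref))
  Fi <- fft(img - mean(img))
  X <- Fi * Conj(Fr) # correlation peak at the shift of img relative to ref
  cc <- Re(fft(X, inverse = TRUE)) / (nr * nc)
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # wrap to signed shifts
  d0 <- c(p[1] - 1, p[2] - 1)
  d0[1] <- if (d0[1] > nr / 2) d0[1] - nr else d0[1]
  d0[2] <- if (d0[2] > nc / 2) d0[2] - nc else d0[2]
  if (upsample <= 1) return(d0)
  # fine grid of +-1 coarse pixel in steps of 1/upsample
  fine <- seq(-1, 1, by = 1 / upsample)
  wr <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1) # FFT frequencies
  wc <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
  er <- exp(2i * pi * outer(d0[1] + fine, wr) / nr)     # |fine| x nr
  ec <- exp(2i * pi * outer(wc, d0[2] + fine) / nc)     # nc x |fine|
  ccf <- Re(er %*% X %*% ec) / (nr * nc)
  q <- which(ccf == max(ccf), arr.ind = TRUE)[1, ]
  c(d0[1] + fine[q[1]], d0[2] + fine[q[2]])
}

#' Estimate rigid in-plane motion
#'
#' Each frame is registered to a reference frame by whole-frame
#' cross-correlation; the correlation peak is refined on a grid `upsample`
#' times finer than the pixel pitch (Fourier upsampling), so displacement
#' estimates are quantised at `pixel_spacing / upsample`. A normalised
#' correlation score at the estimated shift is recorded per frame; frames
#' with undefined correlation (zero variance) are flagged excluded.
#'
#' @param stack a [frame_stack()].
#' @param upsample integer >= 1, sub-pixel refinement factor (default 4).
#' @param reference reference frame index (default: the first frame with
#'   non-zero variance).
#' @return object of class `motion_estimate`: data.frame with columns
#'   `frame`, `d_ax_um`, `d_lat_um`, `correlation`, `excluded`.
#' @export
estimate_rigid_motion <- function(stack, upsample = 4L, reference = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (upsample < 1) stopf("upsample must be >= 1")
  nt <- dim(stack$frames)[3]
  if (is.null(reference)) {
    sds <- apply(stack$frames, 3, sd)
    if (all(sds == 0)) stopf("all frames have zero variance")
    reference <- which(sds > 0)[1]
  }
  ref <- stack$frames[, , reference]
  if (sd(ref) == 0) stopf("reference frame has zero variance")
  d <- matrix(0, nt, 2)
  corr <- rep(NA_real_, nt)
  excl <- rep(FALSE, nt)
  for (f in seq_len(nt)) {
    img <- stack$frames[, , f]
    if (sd(img) == 0) { excl[f] <- TRUE; next }
    if (f == reference) { d[f, ] <- 0; corr[f] <- 1; next }
    # peak of ref (*) img gives the shift of img relative to ref
    pk <- xcorr_peak(ref, img, upsample)
    d[f, ] <- pk * stack$pixel_spacing
    back <- shift_image(img, -pk)
    corr[f] <- suppressWarnings(cor(as.vector(ref), as.vector(back)))
    if (!is.finite(corr[f])) { corr[f] <- NA_real_; excl[f] <- TRUE }
  }
  structure(
    data.frame(frame = seq_len(nt), d_ax_um = d[, 1], d_lat_um = d[, 2],
               correlation = corr, excluded = excl),
    class = c("motion_estimate", "data.frame"),
    reference = reference, upsample = upsample
  )
}

#' Exclude frames with large motion or decorrelation
#'
#' Frames whose displacement magnitude exceeds `displacement_limit` or whose
#' correlation falls below `correlation_floor` are marked excluded: large
#' spikes typically coincide with out-of-plane movement that rigid in-plane
#' compensation cannot repair.
#'
#' @param motion a `motion_estimate`.
#' @param displacement_limit um (default 40).
#' @param correlation_floor minimum similarity score (default 0.8).
#' @return the updated `motion_estimate`.
#' @export
exclude_frames <- function(motion, displacement_limit = 40,
                           correlation_floor = 0.8) {
  stopifnot(inherits(motion, "motion_estimate"))
  mag <- sqrt(motion$d_ax_um^2 + motion$d_lat_um^2)
  bad <- mag > displacement_limit |
    is.na(motion$correlation) | motion$correlation < correlation_floor
  motion$excluded <- motion$excluded | bad
  if (all(motion$excluded)) stopf("no usable frames after exclusion")
  motion
}

#' Compensate rigid motion
#'
#' Translates every retained frame by minus its estimated displacement
#' (bilinear sub-pixel interpolation). Excluded frames stay in the array to
#' preserve frame indexing but are flagged in the returned stack.
#'
#' @param stack a [frame_stack()].
#' @param motion a `motion_estimate` covering all frames.
#' @return a motion-compensated [frame_stack()] with `$excluded` set.
#' @export
compensate_motion <- function(stack, motion) {
  stopifnot(inherits(stack, "frame_stack"), inherits(motion, "motion_estimate"))
  nt <- dim(stack$frames)[3]
  if (nrow(motion) != nt) stopf("motion must cover all frames")
  out <- stack$frames
  for (f in seq_len(nt)) {
    if (motion$excluded[f]) next
    sh <- -c(motion$d_ax_um[f], motion$d_lat_um[f]) / stack$pixel_spacing
    if (any(sh != 0)) out[, , f] <- shift_image(stack$frames[, , f], sh)
  }
  frame_stack(out, stack$frame_rate, stack$pixel_spacing,
              destruction_frame = stack$destruction_frame,
              excluded = motion$excluded)
}

#' Temporal rank-filter background
#'
#' Per pixel and frame, the background is the `rank`-th smallest intensity
#' over a temporal window of +-`half_window` frames centred on the frame
#' (defaults: rank 3 over +-10 frames). Windows are truncated at the
#' sequence ends and the rank is capped at the truncated window length. A
#' low rank tracks the static tissue floor while ignoring the brief bright
#' transits of bubbles. Excluded frames do not contribute to any window;
#' the filter runs on the retained subsequence.
#'
#' @param stack a [frame_stack()].
#' @param rank order statistic (1 = minimum), default 3.
#' @param half_window window half width in frames (default 10).
#' @return a [frame_stack()] of per-frame backgrounds (excluded frames carry
#'   a copy of the nearest retained background).
#' @export
temporal_rank_background <- function(stack, rank = 3L, half_window = 10L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (half_window < 1) stopf("half_window must be >= 1")
  nt <- dim(stack$frames)[3]
  keep <- which(!stack$excluded)
  if (length(keep) < rank) stopf("sequence shorter than rank")
  sub <- stack$frames[, , keep, drop = FALSE]
  d <- dim(sub)
  bg_sub <- rank_filter_cpp(sub, d[1], d[2], d[3], as.integer(rank),
                            as.integer(half_window))
  bg <- array(0, dim = dim(stack$frames))
  bg[, , keep] <- bg_sub
  if (length(keep) < nt) {
    for (f in setdiff(seq_len(nt), keep)) {
      nearest <- keep[which.min(abs(keep - f))]
      bg[, , f] <- bg[, , nearest]
    }
  }
  frame_stack(bg, stack$frame_rate, stack$pixel_spacing,
              destruction_frame = stack$destruction_frame,
              excluded = stack$excluded)
}

#' Foreground by background subtraction
#'
#' Elementwise original minus background, clipped at zero.
#'
#' @param stack,background [frame_stack()] objects of identical shape.
#' @return a [frame_stack()] of foreground intensities.
#' @export
foreground <- function(stack, background) {
  stopifnot(inherits(stack, "frame_stack"), inherits(background, "frame_stack"))
  if (!identical(dim(stack$frames), dim(background$frames))) {
    stopf("stack and background shapes differ")
  }
  frame_stack(pmax(stack$frames - background$frames, 0),
              stack$frame_rate, stack$pixel_spacing,
              destruction_frame = stack$destruction_frame,
              excluded = stack$excluded)
}

#' Calibrate the detection threshold from the destruction event
#'
#' The detection threshold is set to the smallest value yielding zero
#' detections in the bubble-free window right after the destructive pulse:
#' just above the maximum foreground intensity observed there. Without a
#' destruction event a percentile fallback on the earliest retained frames
#' is used, with a warning.
#'
#' @param fg foreground [frame_stack()].
#' @param destruction_frame 1-based frame index of the destructive pulse
#'   (default: taken from the stack; may be `NULL`).
#' @param dead_window number of bubble-free frames after the pulse
#'   (default 10).
#' @param roi optional logical mask restricting the calibration area.
#' @param fallback_quantile percentile used when no destruction event is
#'   available (default 0.999).
#' @param fallback_frames number of early frames for the fallback rule.
#' @return scalar intensity threshold.
#' @export
calibrate_threshold <- function(fg, destruction_frame = fg$destruction_frame,
                                dead_window = 10L, roi = NULL,
                                fallback_quantile = 0.999,
                                fallback_frames = 50L) {
  stopifnot(inherits(fg, "frame_stack"))
  nt <- dim(fg$frames)[3]
  if (is.null(roi)) roi <- matrix(TRUE, dim(fg$frames)[1], dim(fg$frames)[2])
  if (is.null(destruction_frame)) {
    warnf("no destruction event: falling back to the %.1f%% percentile rule",
          100 * fallback_quantile)
    use <- head(which(!fg$excluded), fallback_frames)
    vals <- apply(fg$frames[, , use, drop = FALSE], 3, function(m) m[roi])
    return(as.numeric(quantile(vals, fallback_quantile)))
  }
  win <- destruction_frame:min(nt, destruction_frame + dead_window - 1L)
  if (max(win) > nt) stopf("dead window extends past the sequence")
  win <- win[!fg$excluded[win]]
  m <- max(vapply(win, function(f) {
    v <- fg$frames[, , f][roi]
    if (length(v)) max(v) else 0
  }, numeric(1)))
  m * (1 + 1e-9) + .Machine$double.eps
}

#' Detect microbubbles and localize them at sub-pixel accuracy
#'
#' Per retained frame, supra-threshold foreground pixels inside the ROI are
#' grouped into 8-connected components; each component with at least
#' `min_pixels` pixels becomes one detection whose position is the
#' intensity-weighted centroid in micrometres (sub-pixel). Components
#' touching the ROI boundary are retained.
#'
#' @param fg foreground [frame_stack()].
#' @param threshold intensity threshold (> 0), e.g. from
#'   [calibrate_threshold()].
#' @param roi logical ROI mask (same shape as one frame).
#' @param min_pixels minimum component size (default 2, rejects single-pixel
#'   noise).
#' @return object of class `detection_set`: list with `detections`
#'   (data.frame: frame, ax_um, lat_um, intensity, pixels), `n_frames`,
#'   `roi_mask`, `pixel_spacing`, `frame_rate`, `excluded`.
#' @export
detect_bubbles <- function(fg, threshold, roi = NULL, min_pixels = 2L) {
  stopifnot(inherits(fg, "frame_stack"))
  if (!is.finite(threshold) || threshold <= 0) stopf("threshold must be > 0")
  d <- dim(fg$frames)
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  if (!any(roi)) stopf("empty ROI")
  ax_px <- (seq_len(d[1]) - 1) * fg$pixel_spacing[1]
  lat_px <- (seq_len(d[2]) - 1) * fg$pixel_spacing[2]
  rows <- list()
  for (f in seq_len(d[3])) {
    if (fg$excluded[f]) next
    img <- fg$frames[, , f]
    mask <- img > threshold & roi
    if (!any(mask)) next
    lab <- label8_cpp(mask)
    nlab <- max(lab)
    for (k in seq_len(nlab)) {
      idx <- which(lab == k)
      if (length(idx) < min_pixels) next
      w <- img[idx]
      rc <- arrayInd(idx, d[1:2])
      tot <- sum(w)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f,
        ax_um = sum(w * ax_px[rc[, 1]]) / tot,
        lat_um = sum(w * lat_px[rc[, 2]]) / tot,
        intensity = tot, pixels = length(idx)
      )
    }
  }
  det <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), ax_um = numeric(0), lat_um = numeric(0),
               intensity = numeric(0), pixels = integer(0))
  det <- det[order(det$frame, det$ax_um, det$lat_um), , drop = FALSE]
  rownames(det) <- NULL
  structure(
    list(detections = det, n_frames = d[3], roi_mask = roi,
         pixel_spacing = fg$pixel_spacing, frame_rate = fg$frame_rate,
         excluded = fg$excluded),
    class = "detection_set"
  )
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("detection_set: %d detections over %d frames (%d excluded)\n",
              nrow(x$detections), x$n_frames, sum(x$excluded)))
  invisible(x)
}

#' Write detections to CSV
#' @param det a `detection_set`.
#' @param path output CSV path.
#' @export
write_detections <- function(det, path) {
  write.csv(det$detections, path, row.names = FALSE)
  invisible(path)
}
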