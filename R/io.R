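#' Write a frame stack as multi-page TIFF with JSON sidecar
#'
#' Intensities are scaled into [0, 1] for TIFF storage; the scale factor and
#' the physical calibration (frame rate, pixel spacing, destruction frame,
#' excluded frames) go to a JSON sidecar next to the TIFF.
#'
#' @param stack a [frame_stack()].
#' @param path output path ending in `.tif`; the sidecar is `path` with
#'   `.json` appended.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  mx <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(f) stack$frames[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(frame_rate = stack$frame_rate, pixel_spacing = stack$pixel_spacing,
         destruction_frame = stack$destruction_frame,
         excluded = which(stack$excluded), intensity_scale = mx),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path path to the multi-page TIFF (expects `path.json` sidecar).
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]]); nt <- length(pages)
  frames <- array(0, dim = c(nr, nc, nt))
  for (f in seq_len(nt)) frames[, , f] <- pages[[f]] * meta$intensity_scale
  excluded <- rep(FALSE, nt)
  excluded[meta$excluded] <- TRUE
  frame_stack(frames, meta$frame_rate, meta$pixel_spacing,
              destruction_frame = meta$destruction_frame,
              excluded = excluded)
}

#' Write phantom ground truth as CSV/JSON
#'
#' Segments go to `<prefix>_segments.csv`, per-frame bubble positions to
#' `<prefix>_bubbles.csv`, scalar metadata to `<prefix>_truth.json`.
#'
#' @param truth a `phantom_truth`.
#' @param prefix output path prefix.
#' @export
write_phantom_truth <- function(truth, prefix) {
  segs <- do.call(rbind, lapply(seq_along(truth$segments), function(i) {
    s <- truth$segments[[i]]
    data.frame(segment = i, ax1_um = s$p1[1], lat1_um = s$p1[2],
               ax2_um = s$p2[1], lat2_um = s$p2[2], radius_um = s$radius,
               flow_speed_mm_s = s$flow_speed)
  }))
  write.csv(segs, paste0(prefix, "_segments.csv"), row.names = FALSE)
  write.csv(truth$bubbles, paste0(prefix, "_bubbles.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_frames = truth$n_frames, frame_rate = truth$frame_rate,
         destruction_frame = truth$destruction_frame,
         dead_window = truth$dead_window),
    paste0(prefix, "_truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(prefix)
}
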