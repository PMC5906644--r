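#' Relative blood volume from a track map
#'
#' Fraction of the analysed region covered by bubble tracks. Because tracks
#' are one super-resolution pixel wide, this estimates the areal vessel
#' fraction without the point-spread-function widening that inflates
#' intensity-projection estimates.
#'
#' @param track_map logical track map.
#' @param region_mask logical region mask (same shape).
#' @return fraction in [0, 1].
#' @export
compute_rbv <- function(track_map, region_mask) {
  if (!any(region_mask)) stopf("empty region")
  sum(track_map & region_mask) / sum(region_mask)
}

#' Euclidean distance-to-closest-vessel map
#'
#' Per pixel, the Euclidean distance (um) to the nearest track pixel (track
#' pixels map to zero), computed with the exact Euclidean distance
#' transform.
#'
#' @param track_map logical track map with at least one set pixel.
#' @param pixel_size um per pixel.
#' @return numeric matrix of distances in um.
#' @export
distance_map <- function(track_map, pixel_size) {
  if (!any(track_map)) stopf("no vessels detected")
  d <- EBImage::distmap((!track_map) * 1) # distance to nearest track pixel
  as.matrix(d) * pixel_size
}

.four_stats <- function(v) {
  c(mean = mean(v), variance = mean((v - mean(v))^2), # population variance
    maximum = max(v), median = median(v))
}

#' Distance statistics over a region
#'
#' Mean, population variance, maximum and median of the
#' distance-to-closest-vessel values over the region pixels. Small distances
#' indicate a fine vessel meshwork; a large maximum indicates large
#' unperfused areas.
#'
#' @param dmap distance map in um (from [distance_map()]).
#' @param region_mask logical region mask.
#' @return named numeric vector (mean, variance, maximum, median), um and
#'   um^2.
#' @export
distance_stats <- function(dmap, region_mask) {
  if (!any(region_mask)) stopf("empty region")
  .four_stats(dmap[region_mask])
}

#' Velocity statistics over a region
#'
#' Mean, population variance, maximum and median of the speeds at on-track
#' pixels inside the region. Returns all-NA (with a warning) when the region
#' contains no track pixel.
#'
#' @param velocity_map speed map in mm/s (NA off-track).
#' @param track_map logical track map.
#' @param region_mask logical region mask.
#' @return named numeric vector (mean, variance, maximum, median).
#' @export
velocity_stats <- function(velocity_map, track_map, region_mask) {
  sel <- track_map & region_mask
  if (!any(sel)) {
    warnf("no track pixels in region: velocity statistics undefined")
    return(c(mean = NA_real_, variance = NA_real_, maximum = NA_real_,
             median = NA_real_))
  }
  .four_stats(velocity_map[sel])
}

#' Stratify the track map by flow velocity
#'
#' Splits on-track pixels into a low-velocity and a high-velocity map at a
#' speed threshold (default 0.7 mm/s, the cohort mean of median tumour
#' velocities). Distance statistics computed against each stratum separate
#' the supply architecture of slow capillary-like vessels from fast
#' feeders.
#'
#' @param maps a `superres_maps`.
#' @param threshold speed threshold in mm/s (default 0.7).
#' @return list(low, high) of logical maps partitioning the track pixels.
#' @export
stratify_by_velocity <- function(maps, threshold = 0.7) {
  if (threshold <= 0) stopf("threshold must be > 0")
  on <- maps$track_map
  low <- on & !is.na(maps$velocity_map) & maps$velocity_map < threshold
  high <- on & !is.na(maps$velocity_map) & maps$velocity_map >= threshold
  list(low = low, high = high)
}

#' Velocity threshold from a cohort
#'
#' The mean over tumours of the median on-track velocity, the rule that
#' yields the default 0.7 mm/s stratification threshold.
#'
#' @param median_velocities numeric vector of per-tumour median velocities
#'   (mm/s).
#' @return scalar threshold (mm/s).
#' @export
cohort_velocity_threshold <- function(median_velocities) {
  mean(median_velocities)
}

#' Local flow-direction entropy
#'
#' Tiles the region into square sub-regions (default 25 um, i.e. 5 x 5
#' super-resolution pixels), computes per sub-region the Shannon entropy
#' (base 2) of the histogram of flow directions over `n_bins` equal angular
#' bins, and averages over sub-regions containing at least one track pixel.
#' Predominant local directions give low entropy; locally chaotic flow
#' gives high entropy, bounded by log2(n_bins).
#'
#' @param maps a `superres_maps`.
#' @param region_mask logical region mask (default: the ROI).
#' @param subregion_size tile edge in um; must be a multiple of the map
#'   pixel size (default 25).
#' @param n_bins number of angular bins (default 8).
#' @return mean local entropy in bits, or NA (flagged by a warning) when no
#'   tile contains a track pixel.
#' @export
direction_entropy <- function(maps, region_mask = maps$roi_mask,
                              subregion_size = 25, n_bins = 8L) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  k <- subregion_size / maps$pixel_size
  if (abs(k - round(k)) > 1e-9) {
    stopf("subregion_size must be a multiple of the pixel size")
  }
  k <- as.integer(round(k))
  dirs <- maps$direction_map
  sel <- maps$track_map & region_mask
  nr <- nrow(dirs); nc <- ncol(dirs)
  ents <- numeric(0)
  for (r0 in seq(1, nr, by = k)) {
    for (c0 in seq(1, nc, by = k)) {
      r1 <- min(nr, r0 + k - 1L); c1 <- min(nc, c0 + k - 1L)
      tile_sel <- sel[r0:r1, c0:c1]
      if (!any(tile_sel)) next
      d <- dirs[r0:r1, c0:c1][tile_sel]
      bin <- pmin(pmax(ceiling((d + pi) / (2 * pi / n_bins)), 1L), n_bins)
      p <- tabulate(bin, n_bins)
      p <- p / sum(p)
      p <- p[p > 0]
      ents <- c(ents, -sum(p * log2(p)))
    }
  }
  if (!length(ents)) {
    warnf("no sub-region contains track pixels: entropy undefined")
    return(NA_real_)
  }
  mean(ents)
}

#' Full vascular parameter set for one region
#'
#' Computes the scalar parameter vector of a tumour region from its
#' super-resolution maps: rBV, distance-to-closest-vessel statistics,
#' velocity statistics, distance statistics against the low- and
#' high-velocity vessel strata, and the local flow-direction entropy. The
#' default region is the core, which excludes the large feeding vessels of
#' the rim.
#'
#' @param maps a `superres_maps`.
#' @param region `"core"`, `"rim"` or `"whole"`.
#' @param velocity_threshold stratification threshold in mm/s (default 0.7).
#' @param subregion_size entropy tile edge in um (default 25).
#' @param n_bins entropy angular bins (default 8).
#' @return one-row data.frame with columns `rbv`, `dist_*`, `vel_*`,
#'   `distlow_*`, `disthigh_*` (`mean`, `var`, `max`, `median` each),
#'   `direction_entropy` and `region`. Statistics against an empty stratum
#'   are NA.
#' @export
vascular_params <- function(maps, region = c("core", "rim", "whole"),
                            velocity_threshold = 0.7, subregion_size = 25,
                            n_bins = 8L) {
  region <- match.arg(region)
  mask <- switch(region, core = maps$core_mask, rim = maps$rim_mask,
                 whole = maps$roi_mask)
  if (!any(mask)) {
    if (region == "core") {
      mask <- maps$rim_mask # thin ROI fallback, flagged by split_rim_core
    }
    if (!any(mask)) stopf("empty analysis region")
  }
  ps <- maps$pixel_size
  dist4 <- function(track_map) {
    if (!any(track_map)) {
      return(c(mean = NA_real_, variance = NA_real_, maximum = NA_real_,
               median = NA_real_))
    }
    distance_stats(distance_map(track_map, ps), mask)
  }
  ds <- dist4(maps$track_map)
  vs <- velocity_stats(maps$velocity_map, maps$track_map, mask)
  strata <- stratify_by_velocity(maps, velocity_threshold)
  dl <- dist4(strata$low)
  dh <- dist4(strata$high)
  ent <- direction_entropy(maps, mask, subregion_size, n_bins)
  data.frame(
    rbv = compute_rbv(maps$track_map, mask),
    dist_mean = ds[["mean"]], dist_var = ds[["variance"]],
    dist_max = ds[["maximum"]], dist_median = ds[["median"]],
    vel_mean = vs[["mean"]], vel_var = vs[["variance"]],
    vel_max = vs[["maximum"]], vel_median = vs[["median"]],
    distlow_mean = dl[["mean"]], distlow_var = dl[["variance"]],
    distlow_max = dl[["maximum"]], distlow_median = dl[["median"]],
    disthigh_mean = dh[["mean"]], disthigh_var = dh[["variance"]],
    disthigh_max = dh[["maximum"]], disthigh_median = dh[["median"]],
    direction_entropy = ent, region = region,
    stringsAsFactors = FALSE
  )
}
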