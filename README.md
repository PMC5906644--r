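# ulmtrack

Super-resolution ultrasound localization microscopy (ULM) with a
probabilistic motion model, for quantifying tumour microvasculature from
contrast-enhanced ultrasound (CEUS) cine loops.

Gas-filled microbubbles are intravascular point scatterers: although the
ultrasound point-spread function is tens to hundreds of micrometres wide,
an isolated bubble can be localized to a few micrometres. Linking those
localizations over time reveals the vascular network — vessel by vessel,
with flow speed and direction — at a resolution far beyond the imaging
system's. At clinical bubble concentrations and ordinary frame rates
(~50 Hz), however, nearest-neighbour linking fails wherever vessels cross
or overlap. `ulmtrack` solves the linking problem as Bayesian data
association: it searches for the partition ω of all detections into tracks
and false alarms maximising

> P(ω | Y) ∝ P(Y | ω) · P(ω)

where the likelihood P(Y | ω) of the measured positions Y comes from a
constant-velocity Kalman motion model and the prior P(ω) from the
probabilities of track births, track ends, missed detections and false
alarms. The maximiser is found with a Markov Chain Monte Carlo Data
Association (MCMCDA) sampler, implemented in C++.

The package covers the full chain for a tool of this kind:

* **Phantom** — synthetic CEUS sequences with complete ground truth
  (vessel geometry, bubble trajectories, tissue motion, destruction–
  replenishment), so every downstream stage is testable without scanner
  data: `generate_vessel_network()`, `simulate_bubbles()`,
  `render_frames()`.
* **Preprocessing** — rigid motion estimation/compensation with frame
  exclusion, temporal rank-filter background separation (rank 3 over ±10
  frames), destruction-calibrated adaptive thresholding, intensity-weighted
  sub-pixel centroids: `estimate_rigid_motion()`, `exclude_frames()`,
  `compensate_motion()`, `temporal_rank_background()`, `foreground()`,
  `calibrate_threshold()`, `detect_bubbles()`.
* **Tracking** — `run_mcmcda()`, with `exhaustive_map()` as the
  enumeration oracle on tiny instances, explicit scoring functions
  (`association_log_likelihood()`, `association_log_prior()`), and
  `tracks_to_kinematics()`.
* **Super-resolution maps** — Bresenham rasterization onto a 5 µm grid,
  rim/core ROI split (0.5 mm rim), FWHM resolution estimation under the
  ≥5-passage rule: `rasterize_tracks()`, `split_rim_core()`,
  `estimate_resolution_fwhm()`.
* **Vascular parameters** — relative blood volume (rBV), Euclidean
  distance-to-closest-vessel statistics (overall and stratified at
  0.7 mm/s), velocity statistics, 25 µm local flow-direction entropy:
  `vascular_params()` and friends.
* **Reference methods** — maximum intensity over time (`miot_rbv()`) and
  destruction–replenishment curve fitting (`fit_replenishment()`).
* **Cohort statistics** — one-way ANOVA with Bonferroni post-hoc,
  nearest-neighbour leave-one-out confusion matrices, Pearson correlation
  matrices: `anova_bonferroni()`, `nn_loocv_confusion()`,
  `correlation_matrix()`.
* **Pipeline** — `ulm_config()` / `run_pipeline()` run the whole chain
  from a single seeded configuration and write CSV/TIFF/JSON artifacts
  plus a manifest; `inst/scripts/ulmtrack-cli.R` is a thin command-line
  front end.

## Worked example

Three parallel vessels at 0.5, 0.9 and 1.2 mm/s, imaged for 4 s at 50 Hz
over speckle background and noise, then recovered end to end:

```r
library(ulmtrack)

segments <- list(
  vessel_segment(c(200, 100), c(200, 1100), radius = 20, flow_speed = 0.5),
  vessel_segment(c(450, 100), c(450, 1100), radius = 20, flow_speed = 0.9),
  vessel_segment(c(700, 100), c(700, 1100), radius = 20, flow_speed = 1.2))
truth <- simulate_bubbles(segments, duration = 4, frame_rate = 50,
                          bubble_rate = 10, min_separation = 400, seed = 1)
stack <- render_frames(truth, region_size = c(900, 1200),
                       background_amplitude = 0.3, noise_sigma = 0.02,
                       seed = 2)
stack
#> frame_stack: 78 x 104 pixels, 200 frames @ 50 Hz, 11.6 x 11.6 um/px

background <- temporal_rank_background(stack)   # rank 3 over +-10 frames
fg <- foreground(stack, background)
thr <- calibrate_threshold(fg, NULL)            # percentile fallback (warns)
detections <- detect_bubbles(fg, thr, min_pixels = 2)
detections
#> detection_set: 723 detections over 200 frames (0 excluded)

assoc <- run_mcmcda(detections, motion_model_params(), seed = 3)
assoc
#> association: 24 tracks, 23 false alarms, log posterior -5383.578

kin <- tracks_to_kinematics(assoc)
vessel_row <- c(200, 450, 700)[vapply(kin$steps$ax0_um,
  function(a) which.min(abs(c(200, 450, 700) - a)), integer(1))]
round(vapply(split(kin$steps$speed_mm_s, vessel_row), mean, numeric(1)), 3)
#>   200   450   700
#> 0.500 0.904 1.204
```

The recovered per-vessel mean speeds sit within half a percent of the
designed 0.5/0.9/1.2 mm/s. Rasterizing the tracks and quantifying:

```r
maps <- rasterize_tracks(kin, pixel_size = 5,
                         bounds = list(ax = c(0, 900), lat = c(0, 1200)))
params <- vascular_params(maps, region = "whole")
t(round(params[, 1:9], 3))
#> rbv            0.019
#> dist_mean     81.802
#> dist_var    2503.440
#> dist_max     223.886
#> dist_median   80.000
#> vel_mean       0.974
#> vel_var        0.080
#> vel_max        1.530
#> vel_median     1.020
round(params$direction_entropy, 3)
#> 0.587
```

`rbv` is the fraction of the region covered by 5 µm-wide tracks;
`dist_max` ≈ 224 µm reflects the largest unperfused pocket between the
designed vessels; the low direction entropy (0.587 of a possible 3 bits)
reports the strongly ordered, parallel flow.

A full seeded run — phantom through parameters, reference methods and
manifest — is one call:

```r
res <- run_pipeline(ulm_config(seed = 11,
         phantom = list(background_amplitude = 0.3, noise_sigma = 0.01)),
       output_dir = "run1")
```

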