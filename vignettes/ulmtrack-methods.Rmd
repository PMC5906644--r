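---
title: "Motion-model microbubble tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-model microbubble tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Contrast-enhanced ultrasound (CEUS) images gas-filled microbubbles that are
confined to the blood pool. Individual bubbles act as point scatterers, so
although the imaging point-spread function (PSF) is tens to hundreds of
micrometres wide, the *position* of an isolated bubble can be localized far
below the PSF width. Accumulating thousands of such localizations — and,
crucially, linking them over time into trajectories — yields
super-resolution maps of the vascular network together with per-vessel flow
speed and direction. In tumours this matters because vessel spacing, flow
organisation and perfused fraction distinguish vascular phenotypes that
voxel-scale CEUS post-processing cannot separate.

At clinical contrast doses and conventional frame rates (~50 Hz) many
bubbles are visible per frame, and between two frames a bubble moves a
distance comparable to the spacing between bubbles. Greedy nearest-neighbour
linking then fails systematically wherever vessels cross or run close in the
elevational slab. `ulmtrack` instead treats linking as Bayesian data
association: it seeks the partition $\omega$ of all detections into tracks
and false alarms maximising

$$P(\omega \mid Y) \propto P(Y \mid \omega)\, P(\omega),$$

where $Y$ are the measured positions. $P(Y\mid\omega)$ is the likelihood of
the positions under a linear (constant-velocity) motion model, and
$P(\omega)$ is a prior built from the probabilities of track births, track
terminations, missed detections and false alarms. The maximiser is searched
by a Markov chain over association space (MCMC data association).

## Processing chain

1. **Rigid motion estimation and compensation** (`estimate_rigid_motion`,
   `compensate_motion`). Whole-frame cross-correlation against a reference
   frame, with the correlation peak refined on a grid `upsample` (default 4)
   times finer than the pixel pitch by Fourier upsampling. Frames with
   displacement above `displacement_limit` (default 40 µm) or correlation
   below `correlation_floor` (default 0.8) are excluded
   (`exclude_frames`): large spikes accompany breathing and usually carry
   out-of-plane decorrelation that in-plane translation cannot repair. The
   estimator and the reference choice (first usable frame) are this
   package's choices; only the 4-fold refinement factor is part of the
   reference protocol.
2. **Background separation** (`temporal_rank_background`, `foreground`).
   Per pixel, the background is the rank-3 order statistic over a ±10-frame
   temporal window. A low rank tracks the static speckle floor while a
   bubble's brief bright transit never enters the background. We take the
   rank from the *bottom* of the sorted window; counting from the top would
   let transits leak into the background. Windows are truncated at the
   sequence ends and the rank is capped at the truncated window length.
3. **Detection and localization** (`calibrate_threshold`,
   `detect_bubbles`). The detection threshold is calibrated on the
   destruction–replenishment protocol: the smallest threshold producing
   zero detections in the bubble-free dead window right after the
   destructive pulse. Without a destruction event a 99.9th-percentile
   fallback over early frames is used (with a warning). Supra-threshold
   8-connected components of at least `min_pixels` (default 2) pixels
   become detections at their intensity-weighted centroid, in micrometres,
   sub-pixel.
4. **Tracking** (`run_mcmcda`). See below.
5. **Super-resolution maps** (`rasterize_tracks`). Track steps are drawn
   with Bresenham's line algorithm onto a 5 µm grid (binary track map,
   passage-count map, speed map, direction map), the tumour ROI is split
   into a 0.5 mm rim and a core (`split_rim_core`), and the achieved
   resolution is estimated from cross-profiles of structures passed by at
   least five bubbles (`estimate_resolution_fwhm`).
6. **Vascular parameters** (`vascular_params`): relative blood volume,
   distance-to-closest-vessel statistics (overall and stratified by a
   0.7 mm/s velocity threshold), velocity statistics, and local
   flow-direction entropy over 25 µm sub-regions. The core is the default
   analysis region, excluding the rim's large feeding vessels.
7. **Reference methods** (`miot_rbv`, `fit_replenishment`) and **cohort
   statistics** (`anova_bonferroni`, `nn_loocv_confusion`,
   `correlation_matrix`).

## The association model

**Likelihood.** Axial and lateral dynamics are modelled independently by a
constant-velocity Kalman filter with state (position, velocity). At track
birth the position is initialised at the first measurement with the
measurement variance and the velocity diffusely with standard deviation
`init_velocity_sigma` (default: the gating speed expressed in µm/frame).
Every subsequent detection contributes its innovation log-density; bridged
missed frames propagate the prediction over the corresponding number of
steps. The first detection of a track, and every false alarm, is uniform
over the field-of-view area. Association-independent constants are dropped
throughout, so scores compare partitions of one detection set only.

**Prior.** Per track: one birth factor (intensity `birth_rate` per frame),
`log p_detect` per detection after birth, `log(1 − p_detect)` per missed
interior frame, a geometric survival factor `log(1 − p_terminate)` per
frame spanned and one termination factor. Per false alarm: `log
false_alarm_rate`. With `p_detect > 0.5` extra interior misses always lower
the prior, which is what makes frame-skipping associations unattractive.

**Gating.** A link between detections is admissible only if the implied
speed is at most `max_speed` (default 5 mm/s, an order above typical tumour
capillary flow) plus a 10 µm slack, and the frame gap at most
`max_missed_frames + 1` (default 3). Gates only prune continuations the
likelihood would reject anyway, and bound the proposal neighbourhoods.

**Search.** The chain starts from the all-false-alarm association and
proposes birth/death, extend/reduce, split/merge, track-switch, point-swap
and zip moves, accepting with the Metropolis ratio on the posterior.
Proposal-density corrections are deliberately omitted: the chain is used as
a stochastic maximiser — the highest-posterior association *visited* is
returned — not as a posterior sampler, so detailed balance is not relied
upon. Two details proved load-bearing. First, birth and extension proposals
prefer continuation candidates at the smallest available frame gap.
Second, the zip move merges two tracks whose detections interleave in
time. Without both, the chain reproducibly locks into a local optimum in
which two tracks alternate over one bubble's detections (every link
spanning two frames); such associations are strongly disfavoured by the
miss factors yet unreachable by single-detection moves. The default budget
is `2000 × n_detections` proposals; on tiny instances (≤ 10 detections) the
sampler with a generous budget agrees exactly with exhaustive enumeration
(`exhaustive_map`), which is implemented as the test oracle and refuses
larger inputs. Ties in the posterior are broken towards fewer tracks, then
lexicographically, for determinism.

The per-frame noise parameters default to `process_noise_sigma = 2` µm and
`measurement_noise_sigma = 5` µm: the localization error of an isolated
bubble on our phantoms is well below a micrometre, but residual motion
compensation error and PSF overlap in real data motivate a looser value;
both are plain configuration, not protocol constants.

## Map and parameter conventions

* **Grid.** Physical µm coordinates map to 5 µm pixels by
  `floor((pos − origin)/pixel_size) + 1`, with the grid anchored to the ROI
  bounding box. Matrix rows are axial, columns lateral; directions are
  measured from the +lateral axis, counterclockwise, in (−π, π].
* **Overlap.** Where several passages cross one pixel the speed map stores
  the count-weighted mean speed. For directions an arithmetic mean is
  ill-defined at the ±π wrap, so the direction map stores the circular mean
  (atan2 of the summed unit vectors); the count weighting is preserved
  through the accumulated vectors.
* **Lines across gaps.** Bresenham lines are drawn for every accepted track
  link, including links bridging missed frames; a bridged link is the
  tracker's explicit claim that the bubble traversed that path.
* **Variance.** All summary variances are population variances: the
  statistics summarise the full pixel population of a region, not a sample
  from it.
* **Entropy.** The direction histogram uses 8 equal angular bins (45°) by
  default — no finer than the direction estimates on short tracks warrant —
  and each on-track pixel contributes once (unweighted). Sub-regions with
  no track pixel are excluded from the average rather than counted as zero;
  boundary tiles use their in-region pixels only. The entropy is bounded by
  log2(n_bins) = 3 bits.
* **Rim/core.** The rim is the set of ROI pixels within 0.5 mm (Euclidean)
  of the ROI boundary. If the ROI is so thin that the core is empty the
  analysis falls back to the rim with a warning.
* **Resolution protocol.** A vessel sampled once is trivially one pixel
  wide, so only pixels with ≥ 5 passages seed cross-profiles; the profile
  through each seed is taken along rows and along columns of the count map
  and the narrower interpolated FWHM is kept; the minimum over seeds is the
  reported resolution.

## Reference methods

`miot_rbv` computes the classical maximum-intensity-over-time image (per
pixel: temporal maximum minus temporal median) and segments it by Otsu's
threshold inside the ROI (configurable). Because each PSF-widened blob
marks every pixel it touches, MIOT rBV exceeds the track-based rBV on
matched data — the expected ordering, reproduced in the acceptance checks.

`fit_replenishment` fits the post-destruction mean ROI intensity to the
mono-exponential refill model $A(1 - e^{-\beta t})$, subtracting the
bubble-free dead-window level as baseline (skipped when `dead_window = 0`).
The velocity proxy multiplies $\beta$ by an effective beam-width constant
(default 1 mm) and ignores the beam elevation profile; it is known to
underestimate true bubble speed, and does so on our phantoms because reflow
into the imaging plane is slower than in-plane transit. Non-convergence is
reported, not raised: noisy curves routinely fail to fit.

## Cohort statistics

`anova_bonferroni` runs the one-way ANOVA with pooled-variance pairwise t
tests, multiplying raw p values by the number of pairs (capped at 1), at a
0.05 reporting level. Brown–Forsythe (ANOVA on absolute deviations from
group medians) and per-group Shapiro–Wilk checks at the 0.01 level annotate
the result without gating it. `nn_loocv_confusion` standardises the feature
columns (z-scores; irrelevant for the typical single-parameter use),
classifies each tumour by its nearest neighbour among all others, and
breaks distance ties towards the smallest row index for determinism.

## The synthetic phantom

The generator (`generate_vessel_network`, `simulate_bubbles`,
`render_frames`) is first-class, tested code: it emulates exactly the image
formation the pipeline assumes and records the full ground truth. Straight
vessel segments (radii spanning the 5–40 µm capillary regime, speeds
0.3–1.2 mm/s — bracketing the sub-mm/s flow typical of tumour
microvasculature) carry bubbles arriving at Poisson times, advancing at the
segment speed, with a minimum entry spacing (default 200 µm) standing in
for sparse dosing. Bubbles render as separable anisotropic Gaussians with
FWHM 40 µm axial × 90 µm lateral, the focal resolution of a 40 MHz
preclinical array, on an 11.6 µm pixel raster at 50 Hz. A static speckle
background (low-pass-filtered noise) is generated once and reused across
frames; rigid per-frame displacements, breathing-like spikes with
multiplicative decorrelation noise, additive white noise, and a
destruction–replenishment sequence (destructive pulse, dead window,
Poisson-thinned reflow ramp with time constant `replenish_tau`) are
optional.

What the phantom does **not** emulate: nonlinear bubble oscillation,
attenuation, RF/IQ beamforming, elevational geometry (out-of-plane loss is
at most a dropout stand-in), non-rigid tissue motion, and spatially varying
PSFs. Passing tests on the phantom therefore demonstrate the correctness of
the algorithms under their own model assumptions — localization accuracy,
association optimality, map and parameter arithmetic — not in-vivo image
quality. Absolute in-vivo parameter levels (tumour-model bar charts,
patient rBV) are outside what desk-scale synthetic data can reproduce, and
no test claims them.

Problem sizes were chosen to exercise every code path at interactive cost:
unit phantoms use 1–4 s of 50 Hz video on ~90 × 120 pixel frames
(hundreds to a few thousand detections); the end-to-end recovery phantom
uses ten vessels over 6 s; the reference-method comparison 12 s with a
destruction event at 2 s. The full suite runs in well under a minute of
compute for the unit layer plus ~45 s for the end-to-end layer.

## Numerical and degenerate-input choices

* Rank filter: truncated windows at the ends, rank capped at the window
  length; sequences shorter than the rank are an error.
* Threshold calibration: the threshold sits just above the dead-window
  maximum (relative offset 10⁻⁹), so the dead window yields exactly zero
  detections; an all-zero dead window collapses the threshold to the
  smallest positive step.
* Blank frames (zero variance) cannot be registered and are flagged
  excluded; excluding *all* frames is a hard error.
* Empty detection sets produce an empty association; empty regions,
  empty track maps and all-excluded sequences raise informative errors,
  while empty velocity strata and track-free entropy tiles yield flagged
  `NA`s.
* The exhaustive enumerator refuses more than 10 detections.
* All random stages take explicit integer seeds; the pipeline derives
  per-stage seeds from one root seed.

## Known limitations

* 2-D only: all distances, speeds and directions are in-plane projections.
* Rigid translation only; rotational or non-rigid motion ends up either
  tolerated as noise or excluded.
* The Metropolis search carries no convergence diagnostics; the iteration
  budget is a pragmatic default, and on large, ambiguous detection sets the
  returned association is a good local optimum rather than a certified MAP.
* The replenishment velocity proxy is only as good as its beam-width
  constant; tests assert recovery of $\beta$, not absolute speeds.
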