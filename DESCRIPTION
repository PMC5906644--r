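Package: ulmtrack
Title: Super-Resolution Microbubble Tracking for Contrast-Enhanced
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ultrasound localization microscopy with a probabilistic motion
    model. Detects individual contrast microbubbles in B-mode cine loops
    (rigid motion compensation, temporal rank-filter background separation,
    adaptive-threshold detection, intensity-weighted sub-pixel centroids),
    links the detections into trajectories with Markov Chain Monte Carlo
    Data Association under a constant-velocity Kalman motion model, and
    rasterizes the accepted tracks onto a 5 micrometre grid to produce
    super-resolution vascular maps. From the maps it quantifies relative
    blood volume, distance-to-closest-vessel statistics, velocity
    statistics, velocity-stratified distances and local flow-direction
    entropy, and provides the classical reference analyses (maximum
    intensity over time, destruction-replenishment curve fitting) plus a
    cohort statistics layer (one-way ANOVA with Bonferroni post-hoc,
    nearest-neighbour leave-one-out classification, Pearson correlation
    matrices). A synthetic phantom generator supplies cine loops with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
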