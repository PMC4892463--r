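Package: sptrack
Title: Single-Particle Detection and Tracking for Low-SNR Fluorescence Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection and trajectory linking of fluorescent
    particles in 2D time-lapse microscopy at low signal-to-noise ratios.
    Detection builds a particle probability image from multi-scale Haar-like
    contrast features, extracts soft-thresholded particle-existing regions,
    and segments particles by marker-controlled watershed before sub-pixel
    localization; an adaptive loop refines the five user parameters.
    Trajectories are linked with an interacting multiple model (IMM) Kalman
    filter over random-walk, constant-velocity and constant-acceleration
    motion, with morphology- and intensity-augmented association solved as a
    gated linear-sum assignment. Includes a ground-truthed synthetic movie
    generator (Gaussian spots, Poisson plus additive Gaussian noise), tracking
    evaluation metrics (TPR, FPR, localization RMSE, track-based error,
    Jaccard similarity at detection and track level), and trajectory motion
    analysis (step angles, direction-switching angles, rose histograms, track
    density maps).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    xml2,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
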