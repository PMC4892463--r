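# sptrack

Automated detection and trajectory linking of fluorescent particles in 2D
time-lapse microscopy at low signal-to-noise ratios — the regime of vesicle
tracking under TIRF illumination and single-molecule sptPALM imaging, where
spots are dim, dense in places, and number in the hundreds of thousands.

## What it does

**Detection** builds a *particle probability image* (PPI): multi-scale
Haar-like contrast features (centre–surround square and bar kernels) are
reduced to a per-pixel maximum, the `K = round(F·N·S)` strongest pixels are
classified as particle pixels (`F` an enhancement factor driven by the SNR
estimate and density class), and the PPI at each pixel is the fraction of
particle pixels in a particle-sized window around it. Thresholding the PPI
at 1/e with soft region-local refinement yields *particle-existing regions*
(PERs); markers — local maxima of the lightly smoothed raw frame gated by
the PPI — seed a marker-controlled watershed on the gradient image
restricted to the PERs; particles are localized to sub-pixel precision by
background-subtracted intensity-weighted centroids (or a 2D Gaussian fit
for very small particles). Five user parameters (typical size `S`, minimum
size `s`, expected count `N`, density class, SNR estimate) are refined by
an adaptive search when the detected count disagrees with `N`.

**Linking** runs an interacting multiple model (IMM) Kalman filter — random
walk, constant velocity, constant acceleration — with morphology- and
intensity-augmented state and association. Data association is an exact
gated linear-sum assignment with skip costs; unmatched tracks coast over
short gaps; tracks shorter than three real detections are dropped.

**Evaluation** computes TPR, FPR, localization RMSE, the track-based error

```
E*track = 1 − (Σ_i Y_tracked,i / Y_i) / T_total
```

and Jaccard similarities at detection (JSC) and track (JSCθ) level.

**Motion analysis** measures per-step directions θ₁ and direction-switching
angles θ₂ (θ₂ ≈ 180° is the signature of motion caged in nanodomains),
draws rose-diagram histograms, and accumulates track-density images.

**Simulation** generates ground-truthed movies — Gaussian spots under
Brownian, directed or caged (specular-wall) motion, Poisson + additive
Gaussian camera noise, amplitude calibrated to a requested SNR — so the
whole pipeline is testable without external data.

## Worked example

```r
library(sptrack)

sim <- simulate_movie(40, 20, shape = c(256L, 256L),
                      motion = motion_spec("brownian", step_sd = 0.7),
                      seed = 1, snr = 4)                     # Poisson + N(5, 30) noise
params <- detection_params(S = 12, s = 4, N = 40, density = "low", snr = 4)
det <- detect_stack(sim$stack, params, adaptive = TRUE, carry_n = FALSE)
trk <- link_tracks(det, link_params(max_dist = 5))
evaluate_tracking(trk, sim$truth, matching_spec(2 * sqrt(12 / pi)))
```

```
detections: 610 particle(s) over 20 frame(s)
  mean area 6.6 px, mean peak 156.7 grey levels
tracks: 51 trajectory(ies), 669 points over 20 frames
  length: median 14, range [4, 20]
tracking evaluation
  TPR  0.8363   FPR  0.0000   RMSE 0.7062 px
  JSC  0.8363   JSC_theta 0.3188   E*track 0.2562
  TP 669  FP 0  FN 131  (radius 3.91 px)
```

At SNR 4 the detector recovers 84% of the spots in this sparse field with
no false positives and 0.7 px localization error; the linker reassembles
them into 51 trajectories against 40 ground-truth tracks (fragmentation —
visible in JSCθ, which demands 80% coverage of a truth track — is the main
cost of missed detections). On noise-free movies the same pipeline is
exact: TPR 1, FPR 0, RMSE ≈ 0.03 px, E*track 0.

Motion analysis on the linked tracks:

```r
th2 <- switch_angles(trk)                       # direction-switching angles
rose <- rose_histogram(th2$theta2, domain = c(0, 180))
modal_angle(rose)                               # caged motion puts this near 180
plot(rose)
dens <- track_density(trk, c(256L, 256L))       # tracks per pixel
```

A command-line front end wrapping the same functions ships in
`inst/cli/spt.R` with subcommands `simulate`, `detect`, `track`,
`evaluate`, `analyze` and `run` (full pipeline from a YAML/JSON config).

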