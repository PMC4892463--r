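test_that("Haar features: zero contrast, point response, DC freedom", {
  expect_true(all(compute_haar_features(matrix(5, 16, 16), 9, 4) == 0))
  # single pixel v on zero background, 1-px inner window, 8-px surround
  fr <- matrix(0, 9, 9); fr[5, 5] <- 7
  h <- compute_haar_features(fr, S = 1, s = 1)
  expect_equal(h[5, 5], 7)
  expect_equal(h[5, 6], -7 / 8)
  # adding a constant changes nothing (mean-difference kernels are DC-free)
  set.seed(1)
  fr2 <- matrix(runif(400, 0, 50), 20, 20)
  expect_equal(compute_haar_features(fr2, 12, 4),
               compute_haar_features(fr2 + 123.4, 12, 4),
               tolerance = 1e-9)
})

test_that("Haar features agree with a hand convolution on a 5x5 array", {
  fr <- matrix(0, 5, 5)
  fr[3, 3] <- 10; fr[2, 4] <- 4
  h <- compute_haar_features(fr, S = 1, s = 1)
  # 1-px inner, ring of 8: response = value - mean(8 neighbours)
  for (r in 2:4) for (c in 2:4) {
    nb <- fr[(r - 1):(r + 1), (c - 1):(c + 1)]
    expect_equal(h[r, c], fr[r, c] - (sum(nb) - fr[r, c]) / 8,
                 tolerance = 1e-12)
  }
})

test_that("enhancement factor follows its stated form", {
  expect_equal(enhancement_factor(7, "low"), 1)
  expect_equal(enhancement_factor(1, "high"), 1.75 * 1.5)
  expect_equal(enhancement_factor(1000, "medium"), 1.25)
  # monotone: non-increasing in snr, non-decreasing in density
  snrs <- c(0.5, 1, 2, 4, 7)
  fs <- vapply(snrs, enhancement_factor, numeric(1), density = "low")
  expect_true(all(diff(fs) <= 0))
  expect_true(enhancement_factor(3, "low") <= enhancement_factor(3, "medium"))
  expect_true(enhancement_factor(3, "medium") <= enhancement_factor(3, "high"))
})

test_that("pixel classification selects exactly K pixels with raster ties", {
  set.seed(2)
  haar <- matrix(rnorm(100 * 100), 100, 100)
  p <- detection_params(S = 9, s = 1, N = 1, density = "low", snr = 7)
  bin <- classify_pixels(haar, p)
  expect_equal(sum(bin), 9L)
  # sorting oracle: the selected pixels are the 9 largest values
  expect_equal(sort(haar[bin], decreasing = TRUE),
               sort(as.vector(haar), decreasing = TRUE)[1:9])
  # doubling F doubles K below the cap
  p2 <- p; p2$F <- 2
  expect_equal(sum(classify_pixels(haar, p2)), 18L)
  # all-tied feature image: raster-first selection
  flat <- matrix(0, 10, 10)
  p3 <- detection_params(S = 3, s = 1, N = 1, density = "low", snr = 7)
  b3 <- classify_pixels(flat, p3)
  expect_equal(which(t(b3)), 1:3) # first three raster positions
  # inconsistent parameters rejected
  p4 <- detection_params(S = 100, s = 1, N = 100, density = "low", snr = 7)
  expect_error(classify_pixels(matrix(0, 10, 10), p4), "budget")
})

test_that("PPI is a windowed particle-pixel fraction in [0, 1]", {
  all_p <- matrix(TRUE, 12, 12)
  expect_true(all(compute_ppi(all_p, 9) == 1))
  expect_true(all(compute_ppi(!all_p, 9) == 0))
  b <- matrix(FALSE, 9, 9); b[4, 4] <- b[5, 5] <- b[6, 6] <- TRUE
  expect_equal(compute_ppi(b, 9)[5, 5], 3 / 9)
  set.seed(3)
  for (k in 1:5) {
    rnd <- matrix(runif(400) < 0.3, 20, 20)
    ppi <- compute_ppi(rnd, 12)
    expect_true(all(ppi >= 0 & ppi <= 1))
  }
})

test_that("PER extraction applies the 1/e floor and region-local refinement", {
  expect_equal(max(extract_pers(matrix(0.5, 16, 16), 1)), 1L)
  expect_equal(max(extract_pers(matrix(0.3, 16, 16), 1)), 0L)
  # two touching blobs, peaks 1.0 and 0.5, bridge at ~0.4: refinement splits
  x <- seq_len(41)
  blob <- function(c0, pk) pk * exp(-(outer((x - 21)^2, (x - c0)^2, "+")) / 27.2)
  ppi <- pmin(blob(15, 1.0) + blob(27, 0.5), 1)
  bridge <- ppi[21, 21]
  expect_gt(bridge, exp(-1)) # they really touch above the floor
  expect_lt(bridge, 0.5) # and below half the stronger peak
  lab <- extract_pers(ppi, 1)
  expect_equal(max(lab), 2L)
  # the two peaks carry different labels
  expect_true(lab[21, 15] != lab[21, 27])
  expect_true(all(lab[ppi < exp(-1)] == 0L))
})

test_that("markers sit on smoothed maxima inside PERs", {
  truth <- data.frame(track_id = 1L, frame = 1L, x = 30, y = 20,
                      amplitude = 100, sigma = 1.5)
  fr <- render_frames(truth, background = 5, shape = c(48L, 48L))$frames[[1]]
  p <- detection_params(S = 12, s = 4, N = 1, density = "low", snr = 7)
  haar <- compute_haar_features(fr, p$S, p$s)
  ppi <- compute_ppi(classify_pixels(haar, p), p$S)
  pers <- extract_pers(ppi, p$s)
  mk <- find_markers(fr, pers, ppi, p$s)
  expect_equal(nrow(mk), 1L)
  expect_lte(abs(mk$col - 1 - 30), 1)
  expect_lte(abs(mk$row - 1 - 20), 1)
  # a local maximum outside every PER is not a marker
  fr2 <- fr; fr2[40, 40] <- 60 # bright pixel away from the PER
  mk2 <- find_markers(fr2, pers, ppi, p$s)
  expect_true(all(pers[cbind(mk2$row, mk2$col)] > 0L))
  # constant image within a PER: plateau collapses to one centroid marker
  flat <- matrix(10, 48, 48)
  mk3 <- suppressWarnings(find_markers(flat, pers, ppi, p$s))
  expect_equal(nrow(mk3), max(pers))
})

test_that("watershed respects PERs and separates two-marker regions", {
  # one radially decreasing spot within one circular PER
  x <- seq_len(41)
  fr <- 100 * exp(-(outer((x - 21)^2, (x - 21)^2, "+")) / 60)
  pers <- matrix(0L, 41, 41)
  pers[outer((x - 21)^2, (x - 21)^2, "+") <= 100] <- 1L
  mk <- data.frame(row = 21L, col = 21L, per = 1L)
  seg <- segment_watershed(fr, mk, pers, s = 4)
  expect_equal(seg > 0L, pers > 0L)
  # dumbbell PER with two markers: both segments, partitioning the PER
  fr2 <- 100 * exp(-(outer((x - 21)^2, (x - 14)^2, "+")) / 40) +
    100 * exp(-(outer((x - 21)^2, (x - 28)^2, "+")) / 40)
  pers2 <- matrix(0L, 41, 41)
  pers2[fr2 > 15] <- 1L
  mk2 <- data.frame(row = c(21L, 21L), col = c(14L, 28L), per = c(1L, 1L))
  seg2 <- segment_watershed(fr2, mk2, pers2, s = 4)
  expect_setequal(unique(as.vector(seg2[pers2 > 0L])), c(1L, 2L))
  expect_true(all(seg2[pers2 == 0L] == 0L))
  # the boundary falls at the gradient ridge between the two spots
  expect_true(seg2[21, 14] == 1L && seg2[21, 28] == 2L)
  # markers are mandatory inside PERs
  expect_error(segment_watershed(fr2, data.frame(row = 1L, col = 1L, per = 1L),
                                 pers2, 4), "inside a PER")
})

test_that("localization recovers centres, weights and shapes", {
  # symmetric noise-free spot: centroid error below 0.05 px
  truth <- data.frame(track_id = 1L, frame = 1L, x = 24.3, y = 19.6,
                      amplitude = 100, sigma = 1.5)
  fr <- render_frames(truth, background = 8, shape = c(48L, 48L))$frames[[1]]
  p <- detection_params(S = 12, s = 4, N = 1, density = "low", snr = 7)
  d <- detect_frame(fr, p)
  expect_equal(nrow(d), 1L)
  expect_lt(sqrt((d$x - 24.3)^2 + (d$y - 19.6)^2), 0.05)
  # two-pixel segment, values 10 and 30 on zero background -> x = 0.75
  seg <- matrix(0L, 3, 4); seg[2, 1] <- 1L; seg[2, 2] <- 1L
  frx <- matrix(0, 3, 4); frx[2, 1] <- 10; frx[2, 2] <- 30
  loc <- localize(frx, seg, S = 12, background = 0)
  expect_equal(loc$x, 0.75, tolerance = 1e-12)
  expect_equal(loc$y, 1, tolerance = 1e-12)
  # rasterized disc: circularity within 0.15 of 1, axes near the diameter
  n <- 31; xs <- seq_len(n)
  disc <- matrix(0L, n, n)
  disc[outer((xs - 16)^2, (xs - 16)^2, "+") <= 8^2] <- 1L
  frd <- matrix(1, n, n) + 50 * disc
  locd <- localize(frd, disc, S = 200)
  expect_gt(locd$circularity, 0.85)
  expect_lte(locd$circularity, 1)
  expect_equal(locd$major_axis / locd$minor_axis, 1, tolerance = 0.05)
  expect_equal(locd$major_axis, 16, tolerance = 2)
})

test_that("small-particle branch uses the Gaussian fit", {
  truth <- data.frame(track_id = 1L, frame = 1L, x = 20.37, y = 15.81,
                      amplitude = 120, sigma = 0.9)
  fr <- render_frames(truth, background = 6, shape = c(40L, 40L))$frames[[1]]
  p <- detection_params(S = 6, s = 2, N = 1, density = "low", snr = 7)
  d <- detect_frame(fr, p)
  expect_equal(nrow(d), 1L)
  expect_false(d$fit_fallback)
  expect_lt(sqrt((d$x - 20.37)^2 + (d$y - 15.81)^2), 0.05)
})

test_that("full-frame detection is exact on well-separated noise-free spots", {
  sim <- clean_movie(n_tracks = 10, n_frames = 2, seed = 31)
  p <- detection_params(S = 12, s = 4, N = 10, density = "low", snr = 7)
  d <- detect_frame(sim$stack$frames[[1]], p)
  expect_equal(nrow(d), 10L)
  m <- match_detections(d, sim$truth[sim$truth$frame == 1, ],
                        matching_spec(2))
  expect_equal(m$tp, 10L)
  expect_lte(localization_rmse(m), 0.1)
})

test_that("segment pixels always lie inside PERs and segments are disjoint", {
  set.seed(17)
  for (k in 1:3) {
    sim <- simulate_movie(15, 2, c(96L, 96L), seed = 40 + k, snr = 4)
    fr <- sim$stack$frames[[1]]
    p <- detection_params(S = 12, s = 4, N = 15, density = "low", snr = 4)
    haar <- compute_haar_features(fr, p$S, p$s)
    ppi <- compute_ppi(classify_pixels(haar, p), p$S)
    pers <- extract_pers(ppi, p$s)
    if (max(pers) == 0L) next
    mk <- suppressWarnings(find_markers(fr, pers, ppi, p$s))
    expect_true(all(pers[cbind(mk$row, mk$col)] > 0L))
    seg <- segment_watershed(fr, mk, pers, p$s)
    expect_true(all(pers[seg > 0L] > 0L))
    # each marker's segment (if retained) is unique to it
    labs <- seg[cbind(mk$row, mk$col)]
    labs <- labs[labs > 0L]
    expect_equal(anyDuplicated(labs), 0L)
  }
})

test_that("detection count responds monotonically to the particle budget", {
  sim <- clean_movie(n_tracks = 12, n_frames = 2, seed = 33)
  fr <- sim$stack$frames[[1]]
  haar <- compute_haar_features(fr, 12, 4)
  counts <- vapply(c(7, 4, 2, 1), function(snr) {
    p <- detection_params(S = 12, s = 4, N = 12, density = "low", snr = snr)
    sum(classify_pixels(haar, p))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0)) # K grows as the SNR estimate falls
  dets <- vapply(c(7, 2), function(snr) {
    p <- detection_params(S = 12, s = 4, N = 12, density = "low", snr = snr)
    nrow(detect_frame(fr, p))
  }, numeric(1))
  expect_gte(dets[2], dets[1])
})

test_that("adaptive refinement stops immediately when already in tolerance", {
  sim <- clean_movie(n_tracks = 10, n_frames = 2, seed = 35)
  p <- detection_params(S = 12, s = 4, N = 10, density = "low", snr = 7)
  a <- adapt_params(p, sim$stack$frames[[1]])
  expect_true(a$converged)
  expect_equal(a$iterations, 1L)
  expect_equal(a$params$snr, p$snr)
  expect_equal(a$params$density, p$density)
})

test_that("adaptive refinement recovers the true count from a bad N", {
  sim <- clean_movie(n_tracks = 40, n_frames = 2, shape = c(256L, 256L),
                     seed = 36, min_separation = 12)
  fr <- sim$stack$frames[[1]]
  for (N0 in c(20L, 80L)) { # +/- 50% mis-specification
    p <- detection_params(S = 12, s = 4, N = N0, density = "low", snr = 7)
    a <- suppressWarnings(adapt_params(p, fr))
    expect_lte(a$iterations, 10L)
    expect_lte(abs(nrow(a$detections) - 40) / 40, 0.2)
  }
})
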