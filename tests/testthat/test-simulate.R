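test_that("identical seeds reproduce tracks and noisy stacks bit-exactly", {
  a <- simulate_movie(5, 4, c(64L, 64L), seed = 9)
  b <- simulate_movie(5, 4, c(64L, 64L), seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$stack$frames, b$stack$frames)
  c <- simulate_movie(5, 4, c(64L, 64L), seed = 10)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("zero step sd yields a stationary track", {
  tr <- simulate_tracks(1, 10, c(64L, 64L),
                        motion_spec("brownian", step_sd = 0), seed = 1)
  expect_equal(nrow(tr), 10L)
  expect_equal(length(unique(tr$x)), 1L)
  expect_equal(length(unique(tr$y)), 1L)
})

test_that("track counts and lengths match the requested regime", {
  tr <- simulate_tracks(500, 100, c(512L, 512L), seed = 2)
  expect_equal(length(unique(tr$track_id)), 500L)
  expect_true(all(table(tr$track_id) == 100L))
  # frame indices strictly increasing with unit step
  steps <- tapply(tr$frame, tr$track_id, function(f) all(diff(f) == 1L))
  expect_true(all(steps))
  expect_true(all(tr$x >= 0 & tr$x <= 511 & tr$y >= 0 & tr$y <= 511))
})

test_that("caged tracks never leave their cage", {
  tr <- simulate_tracks(3, 10000, c(64L, 64L),
                        motion_spec("caged", step_sd = 1, cage_radius = 2),
                        seed = 4)
  for (p in split(tr, tr$track_id)) {
    d <- sqrt((p$x - p$x[1])^2 + (p$y - p$y[1])^2)
    expect_lte(max(d), 2 + 1e-9)
  }
})

test_that("density presets scale with image area", {
  expect_equal(density_tracks("low"), 500L)
  expect_equal(density_tracks("medium"), 2500L)
  expect_equal(density_tracks("high"), 5000L)
  expect_equal(density_tracks("medium", c(256L, 256L)), 625L)
})

test_that("minimum separation is honoured or rejected", {
  tr <- simulate_tracks(10, 2, c(128L, 128L), seed = 5, min_separation = 20)
  p1 <- tr[tr$frame == 1, ]
  d <- as.matrix(stats::dist(cbind(p1$x, p1$y)))
  diag(d) <- Inf
  expect_gte(min(d), 20)
  expect_error(simulate_tracks(100, 2, c(32L, 32L), seed = 5,
                               min_separation = 20), "cannot place")
})

test_that("rendering puts the stated peak on a flat background", {
  truth <- data.frame(track_id = 1L, frame = 1L, x = 20, y = 30,
                      amplitude = 80, sigma = 1.5)
  st <- render_frames(truth, background = 12, shape = c(64L, 64L))
  # pixel centre coincides with the spot centre: value = b + A exactly
  expect_equal(st$frames[[1]][31, 21], 92, tolerance = 1e-12)
  # frames with no particles are constant background
  truth2 <- data.frame(track_id = 1L, frame = 2L, x = 20, y = 30,
                       amplitude = 80, sigma = 1.5)
  st2 <- render_frames(truth2, background = 12, shape = c(64L, 64L))
  expect_true(all(st2$frames[[1]] == 12))
})

test_that("rendering is additive for disjoint particles", {
  t1 <- data.frame(track_id = 1L, frame = 1L, x = 15, y = 15,
                   amplitude = 50, sigma = 1.2)
  t2 <- data.frame(track_id = 2L, frame = 1L, x = 45, y = 45,
                   amplitude = 70, sigma = 1.2)
  both <- rbind(t1, t2)
  f1 <- render_frames(t1, background = 0, shape = c(64L, 64L))$frames[[1]]
  f2 <- render_frames(t2, background = 0, shape = c(64L, 64L))$frames[[1]]
  f12 <- render_frames(both, background = 0, shape = c(64L, 64L))$frames[[1]]
  expect_equal(f12, f1 + f2, tolerance = 1e-12)
})

test_that("rendered intensity above background integrates to A * 2 pi sigma^2", {
  truth <- data.frame(track_id = 1:2, frame = 1L, x = c(20, 44),
                      y = c(25, 40), amplitude = c(60, 90),
                      sigma = c(1.2, 1.8))
  st <- render_frames(truth, background = 5, shape = c(64L, 64L))
  total <- sum(st$frames[[1]] - 5)
  expected <- sum(truth$amplitude * 2 * pi * truth$sigma^2)
  expect_equal(total, expected, tolerance = 0.01)
})

test_that("noise model reduces to identity and matches its stated moments", {
  st <- frame_stack(matrix(runif(100, 0, 200), 10, 10))
  out <- add_noise(st, noise_spec(poisson = FALSE, m = 0, sd = 0), seed = 1)
  expect_equal(out$frames[[1]], st$frames[[1]])
  # Poisson of a zero image is identically zero before the Gaussian
  z <- add_noise(frame_stack(matrix(0, 10, 10)),
                 noise_spec(poisson = TRUE, m = 0, sd = 0), seed = 1)
  expect_true(all(z$frames[[1]] == 0))
  # law of large numbers on the stated model: clean 100, Poisson + N(5, 30)
  big <- frame_stack(matrix(100, 1000, 1000))
  noisy <- add_noise(big, noise_spec(TRUE, m = 5, sd = 30, bit_depth = 8L),
                     seed = 2)
  sd_tot <- sqrt(100 + 30^2)
  # clipping at 255 trims the upper tail slightly; allow for that bias
  expect_lt(abs(mean(noisy$frames[[1]]) - 105), 3 * sd_tot / 1000 + 0.05)
})

test_that("measured SNR reflects its construction", {
  truth <- data.frame(track_id = 1L, frame = 1L, x = 32, y = 32,
                      amplitude = 4 * 20, sigma = 1.5)
  # constant background: sd is exactly zero and the guard returns Inf
  flat <- frame_stack(matrix(10, 64, 64))
  expect_equal(measure_snr(flat, truth), Inf)
  clean <- render_frames(truth, background = 0, shape = c(64L, 64L))
  expect_gt(measure_snr(clean, truth), 20) # only the spot tail varies
  set.seed(7)
  reps <- vapply(1:20, function(k) {
    fr <- clean$frames[[1]] + matrix(rnorm(64 * 64, 0, 20), 64, 64)
    measure_snr(frame_stack(fr), truth)
  }, numeric(1))
  expect_equal(mean(reps), 4, tolerance = 0.15)
  # doubling the amplitude doubles the SNR on the same noise realisation
  set.seed(8)
  nz <- matrix(rnorm(64 * 64, 0, 20), 64, 64)
  s1 <- measure_snr(frame_stack(clean$frames[[1]] + nz), truth)
  truth2 <- truth; truth2$amplitude <- 2 * truth$amplitude
  clean2 <- render_frames(truth2, background = 0, shape = c(64L, 64L))
  s2 <- measure_snr(frame_stack(clean2$frames[[1]] + nz), truth2)
  # approximate: the annulus starts at 2 sigma, where the spot tail (13.5%
  # of peak) still inflates the background statistics with the amplitude
  expect_equal(s2 / s1, 2, tolerance = 0.25)
  # border particle: skipped with a warning
  truth_b <- data.frame(track_id = 1L, frame = 1L, x = 2, y = 2,
                        amplitude = 80, sigma = 1.5)
  st_b <- frame_stack(matrix(rnorm(64 * 64, 10, 5), 64, 64))
  expect_warning(measure_snr(st_b, truth_b), "border")
})

test_that("amplitude calibration inverts the background noise model", {
  nz <- noise_spec(TRUE, m = 5, sd = 30)
  expect_equal(amplitude_for_snr(4, 10, nz), 4 * sqrt(10 + 900))
  nz2 <- noise_spec(FALSE, m = 0, sd = 20)
  expect_equal(amplitude_for_snr(3, 50, nz2), 60)
})
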