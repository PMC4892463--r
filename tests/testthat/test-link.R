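test_that("IMM prediction extrapolates each motion model correctly", {
  lp <- link_params(max_dist = 5)
  det <- cv_detections(1)[1, ]
  st <- imm_init(det, lp)
  # stationary particle, random-walk probability 1: prediction = last position
  st_rw <- st; st_rw$mu <- c(1, 0, 0)
  lp_diag <- link_params(max_dist = 5, transition = diag(3))
  pr <- imm_predict(st_rw, lp_diag)
  expect_equal(pr$pred[1:2], c(det$x, det$y), tolerance = 1e-9)
  # constant-velocity probability 1 with a noise-free history: exact
  dets <- cv_detections(6, v = c(2, -1))
  st2 <- imm_init(dets[1, ], lp_diag)
  st2$mu <- c(0, 1, 0)
  for (t in 2:5) {
    pr2 <- imm_predict(st2, lp_diag)
    st2 <- imm_update(st2, pr2, dets[t, ], lp_diag)
    st2$mu <- c(0, 1, 0) # hold the model fixed
  }
  pr2 <- imm_predict(st2, lp_diag)
  expect_equal(pr2$pred[1], dets$x[6], tolerance = 0.05)
  expect_equal(pr2$pred[2], dets$y[6], tolerance = 0.05)
  # equal model probabilities: combined prediction is the cbar-weighted mean
  st3 <- st
  st3$x$cv[3] <- 2 # give the CV model a velocity
  pr3 <- imm_predict(st3, lp_diag)
  per_model <- sapply(pr3$models$x, function(x) x[1])
  expect_equal(pr3$pred[1], sum(pr3$cbar * per_model), tolerance = 1e-9)
})

test_that("association cost is gated, zero at coincidence, monotone", {
  lp <- link_params(max_dist = 5, lambda = 0.5)
  det <- cv_detections(1)[1, ]
  pr <- imm_predict(imm_init(det, lp), lp)
  same <- det
  same$x <- pr$pred[1]; same$y <- pr$pred[2]
  same$area <- pr$pred[3]; same$mean_intensity <- pr$pred[4]
  expect_equal(association_cost(pr, same, lp), 0, tolerance = 1e-9)
  far <- same; far$x <- same$x + 5.01
  expect_identical(association_cost(pr, far, lp), Inf)
  # lambda = 0 reduces to pure Mahalanobis, monotone in displacement
  lp0 <- link_params(max_dist = 50, lambda = 0)
  pr0 <- imm_predict(imm_init(det, lp0), lp0)
  costs <- vapply(seq(0, 4, by = 0.5), function(d) {
    dd <- same; dd$x <- pr0$pred[1] + d; dd$y <- pr0$pred[2]
    dd$area <- 999; dd$mean_intensity <- 1 # must be ignored at lambda = 0
    association_cost(pr0, dd, lp0)
  }, numeric(1))
  expect_equal(costs[1], 0, tolerance = 1e-9)
  expect_true(all(diff(costs) > 0))
})

test_that("assignment is globally optimal and respects the gate", {
  lp <- link_params(max_dist = 5)
  d1 <- cv_detections(1, start = c(10, 10))[1, ]
  d2 <- cv_detections(1, start = c(14, 10))[1, ]
  p1 <- imm_predict(imm_init(d1, lp), lp)
  p2 <- imm_predict(imm_init(d2, lp), lp)
  # detections nearly swapped: optimum is the non-crossing pairing
  dets <- rbind(d1, d2)
  dets$x <- c(12.2, 12.4) # nearer to the other track's naive swap
  asg <- assign_detections(list(p1, p2), dets, lp)
  expect_equal(asg$match, c(1L, 2L))
  # brute force over both pairings confirms
  c11 <- association_cost(p1, dets[1, ], lp)
  c12 <- association_cost(p1, dets[2, ], lp)
  c21 <- association_cost(p2, dets[1, ], lp)
  c22 <- association_cost(p2, dets[2, ], lp)
  expect_lte(c11 + c22, c12 + c21)
  # a detection outside every gate stays unmatched (new track)
  far <- d1; far$x <- 40
  asg2 <- assign_detections(list(p1), far, lp)
  expect_true(is.na(asg2$match[1]))
  expect_equal(asg2$unmatched_detections, 1L)
})

test_that("noise-free parallel tracks are recovered without identity swaps", {
  n <- 12
  a <- cv_detections(n, v = c(2, 0), start = c(5, 10))
  b <- cv_detections(n, v = c(2, 0), start = c(5, 80)) # 70 px apart, gate 7
  dets <- rbind(a, b)
  trk <- link_tracks(dets, link_params(max_dist = 7))
  expect_equal(length(unique(trk$track_id)), 2L)
  expect_true(all(table(trk$track_id) == n))
  truth <- rbind(
    data.frame(track_id = 1, frame = a$frame, x = a$x, y = a$y),
    data.frame(track_id = 2, frame = b$frame, x = b$x, y = b$y))
  expect_equal(track_error(trk, truth, matching_spec(2)), 0)
})

test_that("the minimum-length rule drops 2-frame tracks and keeps 3-frame ones", {
  d2 <- cv_detections(2)
  expect_equal(nrow(link_tracks(d2, link_params(max_dist = 5))), 0L)
  d3 <- cv_detections(3)
  t3 <- link_tracks(d3, link_params(max_dist = 5))
  expect_equal(nrow(t3), 3L)
  expect_equal(length(unique(t3$track_id)), 1L)
})

test_that("a single missed detection is bridged by a flagged coasted point", {
  d <- cv_detections(6)
  d <- d[d$frame != 4, ]
  trk <- link_tracks(d, link_params(max_dist = 5, max_gap = 1))
  expect_equal(length(unique(trk$track_id)), 1L)
  expect_equal(nrow(trk), 6L)
  expect_equal(trk$frame[trk$interpolated], 4)
  # with no gap allowance the track splits and the 2-frame tail is dropped
  trk0 <- link_tracks(d, link_params(max_dist = 5, max_gap = 0L))
  expect_equal(length(unique(trk0$track_id)), 1L)
  expect_equal(nrow(trk0), 3L)
})

test_that("model probabilities stay on the simplex at every step", {
  set.seed(60)
  d <- cv_detections(10, v = c(1.5, 0.5))
  d$x <- d$x + rnorm(10, 0, 0.2); d$y <- d$y + rnorm(10, 0, 0.2)
  trk <- link_tracks(d, link_params(max_dist = 5))
  mu_sum <- trk$model_rw + trk$model_cv + trk$model_ca
  expect_true(all(abs(mu_sum - 1) < 1e-9))
  expect_true(all(trk$model_rw >= 0 & trk$model_cv >= 0 & trk$model_ca >= 0))
})

test_that("detection order within a frame does not change the track set", {
  set.seed(61)
  dets <- do.call(rbind, lapply(1:3, function(id) {
    cv_detections(8, v = c(runif(1, -2, 2), runif(1, -2, 2)),
                  start = c(20 + 30 * id, 50))
  }))
  trk1 <- link_tracks(dets, link_params(max_dist = 6))
  perm <- dets[order(dets$frame, -dets$x), ]
  trk2 <- link_tracks(perm, link_params(max_dist = 6))
  key <- function(tr) {
    s <- split(tr[, c("frame", "x", "y")], tr$track_id)
    s <- lapply(s, function(p) {
      p <- p[order(p$frame), ]
      rownames(p) <- NULL
      p
    })
    unname(s[order(vapply(s, function(p) p$x[1] + 1e6 * p$y[1], numeric(1)))])
  }
  expect_equal(key(trk1), key(trk2), tolerance = 1e-9)
})

test_that("no detection is shared between tracks", {
  set.seed(62)
  sim <- clean_movie(n_tracks = 12, n_frames = 6, shape = c(128L, 128L),
                     seed = 63, min_separation = 14, step_sd = 1)
  det <- detect_stack(sim$stack,
                      detection_params(12, 4, 12, "low", 7), carry_n = FALSE)
  trk <- link_tracks(det, link_params(max_dist = 6))
  real <- trk[!trk$interpolated, ]
  expect_equal(anyDuplicated(real[, c("frame", "x", "y")]), 0L)
})

test_that("the constant-velocity model is identified within five steps", {
  # velocities above the random-walk process-noise scale (max_dist / 3), so
  # directed and diffusive motion are distinguishable at all
  set.seed(64)
  wins <- 0L
  for (k in 1:20) {
    ang <- runif(1, 0, 2 * pi)
    speed <- runif(1, 2, 3.5)
    v <- speed * c(cos(ang), sin(ang))
    d <- cv_detections(7, v = v, start = c(50, 50))
    trk <- link_tracks(d, link_params(max_dist = 6))
    mu_cv <- trk$model_cv[trk$frame <= 6] # first five update steps
    if (max(mu_cv) > 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
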