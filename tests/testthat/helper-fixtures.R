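# Shared fixtures, built in code at test time.

# noise-free movie of well-separated Gaussian spots
clean_movie <- function(n_tracks = 10, n_frames = 3, shape = c(128L, 128L),
                        seed = 3, amplitude = 100, step_sd = 0.5,
                        min_separation = 15) {
  simulate_movie(n_tracks, n_frames, shape = shape,
                 motion = motion_spec("brownian", step_sd = step_sd),
                 seed = seed, snr = NULL, noise = NULL,
                 amplitude = amplitude, min_separation = min_separation)
}

# detections table for a single particle moving at constant velocity
cv_detections <- function(n = 8, v = c(2, 0), start = c(10, 20),
                          area = 10, intensity = 50) {
  do.call(rbind, lapply(seq_len(n), function(t) {
    data.frame(frame = t, x = start[1] + v[1] * (t - 1),
               y = start[2] + v[2] * (t - 1), area = area,
               circularity = 1, major_axis = 3, minor_axis = 3,
               mean_intensity = intensity, peak_intensity = 2 * intensity,
               label = 1L, fit_fallback = FALSE)
  }))
}

# exhaustive-permutation linear-assignment oracle (small matrices only)
brute_lap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= 6, m <= 6)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  if (n <= m) {
    for (p in perms(seq_len(m))) {
      cst <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
      if (cst < best) best <- cst
    }
  } else {
    for (p in perms(seq_len(n))) {
      cst <- sum(cost[cbind(p[seq_len(m)], seq_len(m))])
      if (cst < best) best <- cst
    }
  }
  best
}

# brute-force track-error oracle: enumerate all one-to-one pairings of truth
# tracks to estimated tracks and take the pairing minimising E*track
brute_track_error <- function(est, truth, radius) {
  tids <- unique(truth$track_id)
  eids <- unique(est$track_id)
  y_total <- as.integer(table(truth$track_id)[as.character(tids)])
  counts <- matrix(0, length(tids), length(eids))
  for (i in seq_along(tids)) {
    g <- truth[truth$track_id == tids[i], ]
    for (j in seq_along(eids)) {
      e <- est[est$track_id == eids[j], ]
      k <- match(g$frame, e$frame)
      ok <- !is.na(k)
      if (any(ok)) {
        d2 <- (g$x[ok] - e$x[k[ok]])^2 + (g$y[ok] - e$y[k[ok]])^2
        counts[i, j] <- sum(d2 <= radius^2)
      }
    }
  }
  nt <- length(tids); ne <- length(eids)
  sel <- function(i, used) {
    if (i > nt) return(0)
    best <- sel(i + 1L, used) # truth track i left unpaired
    for (j in seq_len(ne)) {
      if (!used[j]) {
        used2 <- used; used2[j] <- TRUE
        best <- max(best, counts[i, j] / y_total[i] + sel(i + 1L, used2))
      }
    }
    best
  }
  1 - sel(1L, rep(FALSE, ne)) / nt
}

# random track-set pair for the track-error oracle suite
random_trackset <- function(seed) {
  set.seed(seed)
  mk <- function(ids) {
    if (length(ids) == 0L) {
      return(data.frame(track_id = integer(0), frame = integer(0),
                        x = numeric(0), y = numeric(0)))
    }
    do.call(rbind, lapply(ids, function(id) {
      n <- sample(3:8, 1)
      f0 <- sample(1:3, 1)
      data.frame(track_id = id, frame = f0:(f0 + n - 1L),
                 x = cumsum(stats::runif(n, -2, 2)) + stats::runif(1, 0, 20),
                 y = cumsum(stats::runif(n, -2, 2)) + stats::runif(1, 0, 20))
    }))
  }
  list(truth = mk(seq_len(sample(1:4, 1))),
       est = mk(seq_len(sample(0:4, 1))))
}
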