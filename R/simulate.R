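# Synthetic movie generator: ground-truthed Gaussian-spot movies with
# Brownian, directed or caged (nanodomain-confined) motion, corrupted by
# Poisson shot noise plus additive Gaussian read noise.

#' Motion model specification
#'
#' @param model one of `"brownian"`, `"directed"`, `"caged"`.
#' @param step_sd per-axis diffusion step standard deviation, pixels/frame.
#' @param drift drift velocity `c(vx, vy)` in pixels/frame (directed motion).
#' @param cage_radius confinement radius in pixels (caged motion only).
#' @return an object of class `motion_spec`.
#' @export
motion_spec <- function(model = c("brownian", "directed", "caged"),
                        step_sd = 1, drift = c(0, 0), cage_radius = NULL) {
  model <- match.arg(model)
  stopifnot(step_sd >= 0, length(drift) == 2L)
  if (model == "caged") {
    if (is.null(cage_radius) || cage_radius <= 0) {
      stop("caged motion requires cage_radius > 0")
    }
  }
  structure(list(model = model, step_sd = step_sd, drift = as.numeric(drift),
                 cage_radius = cage_radius), class = "motion_spec")
}

#' Camera noise specification
#'
#' Poisson shot noise on the clean signal followed by additive Gaussian read
#' noise, clipped to the bit-depth range.
#'
#' @param poisson logical; apply Poisson noise to the clean pixel values.
#' @param m Gaussian noise mean, grey levels.
#' @param sd Gaussian noise standard deviation, grey levels.
#' @param bit_depth sensor bit depth (8 or 16).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(poisson = TRUE, m = 5, sd = 30, bit_depth = 8L) {
  stopifnot(sd >= 0, bit_depth %in% c(8L, 16L))
  structure(list(poisson = poisson, m = m, sd = sd,
                 bit_depth = as.integer(bit_depth)), class = "noise_spec")
}

# Specular (billiard) reflection of a step inside a disc of radius R around
# `centre`: the segment from p to p + step is reflected elastically off the
# circular wall, possibly several times; the particle can never leave the
# cage. Elastic wall collisions are what makes confined motion reverse its
# direction (the theta2 ~ 180 degree signature).
#' @keywords internal
reflect_in_disc <- function(p, step, centre, R) {
  q <- p + step
  for (it in 1:20) {
    d <- q - centre
    if (sum(d^2) <= R^2) return(q)
    # intersection of p -> q with the circle
    u <- q - p
    a <- sum(u^2)
    if (a < 1e-30) break
    b <- 2 * sum((p - centre) * u)
    cc <- sum((p - centre)^2) - R^2
    disc <- b^2 - 4 * a * cc
    if (disc < 0) break
    tt <- (-b + sqrt(disc)) / (2 * a)
    tt <- min(max(tt, 0), 1)
    h <- p + tt * u
    n <- (h - centre) / sqrt(sum((h - centre)^2))
    v <- q - h
    q2 <- h + (v - 2 * sum(v * n) * n)
    p <- h - 1e-12 * n # nudge inward to avoid re-hitting the same point
    q <- q2
  }
  # numerical fallback: clamp radially just inside the wall
  d <- q - centre
  centre + d / sqrt(sum(d^2)) * (R * (1 - 1e-12))
}

#' @keywords internal
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

#' Simulate ground-truth particle tracks
#'
#' Generates `n_tracks` trajectories over `n_frames` frames inside an image of
#' `shape = c(height, width)` pixels. Positions are 0-based pixel-centre
#' coordinates (x = column, y = row) and are kept inside the image by
#' reflection; caged tracks are confined to a disc of `cage_radius` around
#' their start point by specular (billiard) reflection off the cage wall, so
#' they can never leave the cage.
#'
#' @param n_tracks number of tracks (>= 1).
#' @param n_frames number of frames (>= 2).
#' @param shape image extent `c(height, width)` in pixels.
#' @param motion a [motion_spec()].
#' @param seed integer seed; identical seeds reproduce tracks exactly.
#' @param amplitude spot peak amplitude above background, grey levels
#'   (recycled across tracks).
#' @param psf_sigma Gaussian point-spread sigma, pixels.
#' @param min_separation optional minimum distance between initial positions,
#'   pixels; an error is raised if the field cannot accommodate it.
#' @param margin border margin for initial positions, pixels.
#' @return a `ground_truth` data.frame with columns
#'   `track_id, frame, x, y, amplitude, sigma`.
#' @export
simulate_tracks <- function(n_tracks, n_frames, shape = c(512L, 512L),
                            motion = motion_spec("brownian"), seed = 1L,
                            amplitude = 100, psf_sigma = 1.2,
                            min_separation = NULL, margin = NULL) {
  stopifnot(n_tracks >= 1, n_frames >= 2, length(shape) == 2L)
  if (is.null(margin)) margin <- ceiling(3 * psf_sigma)
  h <- shape[1L]; w <- shape[2L]
  if (w - 1 - 2 * margin <= 0 || h - 1 - 2 * margin <= 0) {
    stop("image shape too small for the requested margin")
  }
  set.seed(as.integer(seed))
  # initial positions (optionally with a minimum pairwise separation)
  x0 <- numeric(n_tracks); y0 <- numeric(n_tracks)
  placed <- 0L; attempts <- 0L
  max_attempts <- 200L * n_tracks
  while (placed < n_tracks) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("cannot place ", n_tracks, " tracks with min_separation = ",
           min_separation, " in a ", h, "x", w, " field")
    }
    px <- stats::runif(1, margin, w - 1 - margin)
    py <- stats::runif(1, margin, h - 1 - margin)
    if (!is.null(min_separation) && placed > 0L) {
      d2 <- (x0[seq_len(placed)] - px)^2 + (y0[seq_len(placed)] - py)^2
      if (min(d2) < min_separation^2) next
    }
    placed <- placed + 1L
    x0[placed] <- px; y0[placed] <- py
  }
  amplitude <- rep_len(amplitude, n_tracks)
  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    dx <- stats::rnorm(n_frames - 1L, 0, motion$step_sd)
    dy <- stats::rnorm(n_frames - 1L, 0, motion$step_sd)
    if (motion$model == "directed") {
      dx <- dx + motion$drift[1L]
      dy <- dy + motion$drift[2L]
    }
    if (motion$model == "caged") {
      x <- numeric(n_frames); y <- numeric(n_frames)
      x[1L] <- x0[i]; y[1L] <- y0[i]
      R <- motion$cage_radius
      for (t in seq_len(n_frames - 1L)) {
        q <- reflect_in_disc(c(x[t], y[t]), c(dx[t], dy[t]),
                             c(x0[i], y0[i]), R)
        x[t + 1L] <- q[1L]; y[t + 1L] <- q[2L]
      }
    } else {
      x <- reflect_into(x0[i] + c(0, cumsum(dx)), 0, w - 1)
      y <- reflect_into(y0[i] + c(0, cumsum(dy)), 0, h - 1)
    }
    out[[i]] <- data.frame(track_id = i, frame = seq_len(n_frames),
                           x = x, y = y, amplitude = amplitude[i],
                           sigma = psf_sigma)
  }
  truth <- do.call(rbind, out)
  attr(truth, "shape") <- as.integer(shape)
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

#' Render noise-free frames from ground truth
#'
#' Each particle is drawn as an isotropic 2D Gaussian of its stated sigma and
#' peak amplitude, added to a flat background. Off-image tails are clipped
#' silently.
#'
#' @param truth a `ground_truth` table ([simulate_tracks()]).
#' @param background flat background level, grey levels.
#' @param shape image extent `c(height, width)`; defaults to the truth's.
#' @param bit_depth bit depth recorded on the stack (no clipping is applied
#'   here; the frames are noise-free and continuous).
#' @return a `frame_stack`.
#' @export
render_frames <- function(truth, background = 10, shape = NULL,
                          bit_depth = 8L) {
  stopifnot(nrow(truth) > 0L)
  if (is.null(shape)) shape <- attr(truth, "shape")
  if (is.null(shape)) stop("image shape must be supplied")
  h <- shape[1L]; w <- shape[2L]
  n_frames <- max(truth$frame)
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    f <- matrix(background, h, w)
    rows <- which(truth$frame == t)
    for (k in rows) {
      s <- truth$sigma[k]
      A <- truth$amplitude[k]
      cx <- truth$x[k]; cy <- truth$y[k]
      rad <- ceiling(4 * s)
      c1 <- max(1L, floor(cx + 1 - rad)); c2 <- min(w, ceiling(cx + 1 + rad))
      r1 <- max(1L, floor(cy + 1 - rad)); r2 <- min(h, ceiling(cy + 1 + rad))
      if (c1 > c2 || r1 > r2) next
      gx <- exp(-((c1:c2) - 1 - cx)^2 / (2 * s^2))
      gy <- exp(-((r1:r2) - 1 - cy)^2 / (2 * s^2))
      f[r1:r2, c1:c2] <- f[r1:r2, c1:c2] + A * outer(gy, gx)
    }
    frames[[t]] <- f
  }
  frame_stack(frames, bit_depth = bit_depth)
}

#' Add Poisson + Gaussian camera noise
#'
#' Per pixel: a Poisson draw with mean equal to the clean value, then an
#' additive Gaussian draw (mean `m`, sd `sd`), then clipping to the bit-depth
#' range `[0, 2^bits - 1]`.
#'
#' @param stack a noise-free `frame_stack`.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return a `frame_stack` of the same shape.
#' @export
add_noise <- function(stack, noise = noise_spec(), seed = 1L) {
  set.seed(as.integer(seed))
  top <- 2^noise$bit_depth - 1
  frames <- lapply(stack$frames, function(f) {
    v <- as.vector(f)
    if (noise$poisson) v <- stats::rpois(length(v), pmax(v, 0))
    if (noise$sd > 0 || noise$m != 0) {
      v <- v + stats::rnorm(length(v), noise$m, noise$sd)
    }
    matrix(pmin(pmax(v, 0), top), nrow(f), ncol(f))
  })
  frame_stack(frames, bit_depth = noise$bit_depth,
              frame_interval = stack$frame_interval,
              pixel_size = stack$pixel_size)
}

#' Spot amplitude realising a requested SNR
#'
#' Inverts the Poisson + Gaussian noise model at the background level: the
#' local background noise sd is `sqrt(background + sd^2)` (Poisson variance
#' plus read noise), so `amplitude = snr * sd_background`.
#'
#' @param snr target signal-to-noise ratio.
#' @param background flat background level, grey levels.
#' @param noise a [noise_spec()].
#' @return peak amplitude in grey levels.
#' @export
amplitude_for_snr <- function(snr, background = 10, noise = noise_spec()) {
  stopifnot(snr > 0)
  var_bg <- noise$sd^2 + if (noise$poisson) background else 0
  snr * sqrt(var_bg)
}

#' Measure the image SNR against ground truth
#'
#' Per particle: `(peak - mean(background)) / sd(background)` with the
#' background taken from an annulus of inner radius `2 * sigma` and outer
#' radius `4 * sigma` around the true position; the values are averaged over
#' all particles. Particles whose annulus crosses the image border are
#' skipped with a warning.
#'
#' @param stack a `frame_stack`.
#' @param truth a `ground_truth` table.
#' @param inner,outer annulus radii in units of the particle's psf sigma.
#' @return mean SNR over measurable particles; `Inf` on a noise-free image.
#' @export
measure_snr <- function(stack, truth, inner = 2, outer = 4) {
  stopifnot(nrow(truth) > 0L)
  h <- nrow(stack$frames[[1L]]); w <- ncol(stack$frames[[1L]])
  snrs <- numeric(0)
  skipped <- 0L
  for (k in seq_len(nrow(truth))) {
    t <- truth$frame[k]
    if (t > length(stack$frames)) next
    f <- stack$frames[[t]]
    s <- truth$sigma[k]
    cx <- truth$x[k]; cy <- truth$y[k]
    ro <- outer * s
    if (cx - ro < 0 || cx + ro > w - 1 || cy - ro < 0 || cy + ro > h - 1) {
      skipped <- skipped + 1L
      next
    }
    rad <- ceiling(ro)
    cc <- (floor(cx) - rad):(ceiling(cx) + rad) + 1L
    rr <- (floor(cy) - rad):(ceiling(cy) + rad) + 1L
    cc <- cc[cc >= 1L & cc <= w]; rr <- rr[rr >= 1L & rr <= h]
    d2 <- outer((rr - 1 - cy)^2, (cc - 1 - cx)^2, "+")
    patch <- f[rr, cc, drop = FALSE]
    bg <- patch[d2 > (inner * s)^2 & d2 <= ro^2]
    pk <- max(patch[d2 <= 1.5^2]) # peak near the true centre
    bsd <- stats::sd(bg)
    snrs <- c(snrs, if (bsd == 0) Inf else (pk - mean(bg)) / bsd)
  }
  if (skipped > 0L) {
    warning(skipped, " particle(s) too close to the border for an annulus; skipped")
  }
  if (length(snrs) == 0L) return(NA_real_)
  mean(snrs)
}

#' Density presets matching the benchmark regimes
#'
#' Track counts for the low/medium/high particle-density regimes on a
#' 512 x 512 field (500, 2500 and 5000 tracks respectively), scaled to the
#' requested image area.
#'
#' @param density `"low"`, `"medium"` or `"high"`.
#' @param shape image extent `c(height, width)`.
#' @return number of tracks (integer).
#' @export
density_tracks <- function(density = c("low", "medium", "high"),
                           shape = c(512L, 512L)) {
  density <- match.arg(density)
  base <- c(low = 500, medium = 2500, high = 5000)[[density]]
  max(1L, as.integer(round(base * prod(shape) / 512^2)))
}

#' Simulate a complete ground-truthed movie
#'
#' Convenience wrapper: tracks, noise-free rendering, amplitude calibration
#' from a requested SNR, and camera noise.
#'
#' @inheritParams simulate_tracks
#' @param snr target signal-to-noise ratio (sets the spot amplitude via
#'   [amplitude_for_snr()]); `NULL` keeps `amplitude`.
#' @param background flat background level, grey levels.
#' @param noise a [noise_spec()], or `NULL` for a noise-free movie.
#' @param amplitude peak amplitude when `snr` is `NULL`.
#' @return list with elements `stack` (noisy), `clean` (noise-free) and
#'   `truth`.
#' @export
simulate_movie <- function(n_tracks, n_frames, shape = c(256L, 256L),
                           motion = motion_spec("brownian"), seed = 1L,
                           snr = 4, background = 10, noise = noise_spec(),
                           psf_sigma = 1.2, amplitude = 100,
                           min_separation = NULL) {
  if (!is.null(snr) && !is.null(noise)) {
    amplitude <- amplitude_for_snr(snr, background, noise)
  }
  truth <- simulate_tracks(n_tracks, n_frames, shape, motion, seed,
                           amplitude = amplitude, psf_sigma = psf_sigma,
                           min_separation = min_separation)
  bit <- if (is.null(noise)) 8L else noise$bit_depth
  clean <- render_frames(truth, background = background, shape = shape,
                         bit_depth = bit)
  stack <- if (is.null(noise)) clean else add_noise(clean, noise, seed = seed + 1L)
  list(stack = stack, clean = clean, truth = truth)
}
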