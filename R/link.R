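# Trajectory linking with an interacting multiple model (IMM) Kalman filter:
# a bank of random-walk, constant-velocity and constant-acceleration filters
# mixed by evolving model probabilities, with gated morphology- and
# intensity-augmented association solved as a linear-sum assignment.
#
# All three models share one 8-dimensional state
#   (x, y, vx, vy, ax, ay, area, intensity)
# with model-specific transition matrices (the random-walk model zeroes the
# velocity and acceleration terms, the constant-velocity model the
# acceleration terms); area and intensity evolve as random walks. The
# measurement is (x, y, area, intensity).

#' Linking parameters
#'
#' @param max_dist maximum linking distance in pixels (association gate).
#' @param min_length minimum number of real detections for a track to be
#'   kept (default 3 frames).
#' @param max_gap maximum number of consecutive missed frames bridged by
#'   coasting on the predicted state.
#' @param lambda weight of the morphology/intensity term in the association
#'   cost.
#' @param transition 3x3 model transition probability matrix (rows sum to 1;
#'   order random walk, constant velocity, constant acceleration).
#' @param process_sd process noise scale, pixels/frame; defaults to
#'   `max_dist / 3`.
#' @param meas_sd measurement (localization) noise sd, pixels.
#' @return an object of class `link_params`.
#' @export
link_params <- function(max_dist = 5, min_length = 3L, max_gap = 1L,
                        lambda = 0.5, transition = NULL, process_sd = NULL,
                        meas_sd = 0.5) {
  stopifnot(max_dist > 0, min_length >= 2L, max_gap >= 0L, lambda >= 0,
            meas_sd > 0)
  if (is.null(transition)) {
    transition <- matrix(0.1, 3L, 3L)
    diag(transition) <- 0.8
  }
  stopifnot(all(dim(transition) == c(3L, 3L)),
            all(abs(rowSums(transition) - 1) < 1e-9))
  if (is.null(process_sd)) process_sd <- max_dist / 3
  structure(list(max_dist = max_dist, min_length = as.integer(min_length),
                 max_gap = as.integer(max_gap), lambda = lambda,
                 transition = transition, process_sd = process_sd,
                 meas_sd = meas_sd),
            class = "link_params")
}

# model transition matrices over the shared 8-dim state
#' @keywords internal
imm_model_matrices <- function() {
  F_rw <- diag(c(1, 1, 0, 0, 0, 0, 1, 1))
  F_cv <- diag(c(1, 1, 1, 1, 0, 0, 1, 1))
  F_cv[1L, 3L] <- 1; F_cv[2L, 4L] <- 1
  F_ca <- diag(8L)
  F_ca[1L, 3L] <- 1; F_ca[2L, 4L] <- 1
  F_ca[1L, 5L] <- 0.5; F_ca[2L, 6L] <- 0.5
  F_ca[3L, 5L] <- 1; F_ca[4L, 6L] <- 1
  H <- matrix(0, 4L, 8L)
  H[1L, 1L] <- 1; H[2L, 2L] <- 1; H[3L, 7L] <- 1; H[4L, 8L] <- 1
  list(F = list(rw = F_rw, cv = F_cv, ca = F_ca), H = H)
}

#' @keywords internal
imm_noise <- function(params, ref_a, ref_i) {
  q <- params$process_sd^2
  qa <- (0.15 * max(ref_a, 1))^2
  qi <- (0.15 * max(ref_i, 1e-6))^2
  eps <- 1e-6
  Q <- list(
    rw = diag(c(q, q, eps, eps, eps, eps, qa, qi)),
    cv = diag(c(q / 4, q / 4, q / 2, q / 2, eps, eps, qa, qi)),
    ca = diag(c(q / 4, q / 4, q / 4, q / 4, q / 2, q / 2, qa, qi)))
  R <- diag(c(params$meas_sd^2, params$meas_sd^2,
              (0.25 * max(ref_a, 1))^2, (0.25 * max(ref_i, 1e-6))^2))
  list(Q = Q, R = R)
}

#' Initialise an IMM state from a detection
#'
#' Velocity and acceleration start at zero with inflated covariance; model
#' probabilities start uniform.
#'
#' @param detection one-row detection (needs `x`, `y`, `area`,
#'   `mean_intensity`).
#' @param params a [link_params()].
#' @return an object of class `imm_state`.
#' @export
imm_init <- function(detection, params) {
  x0 <- c(detection$x, detection$y, 0, 0, 0, 0,
          detection$area, detection$mean_intensity)
  nz <- imm_noise(params, detection$area, detection$mean_intensity)
  P0 <- diag(c(params$meas_sd^2, params$meas_sd^2,
               params$max_dist^2, params$max_dist^2,
               (params$max_dist / 2)^2, (params$max_dist / 2)^2,
               nz$R[3L, 3L], nz$R[4L, 4L]))
  structure(list(x = list(rw = x0, cv = x0, ca = x0),
                 P = list(rw = P0, cv = P0, ca = P0),
                 mu = rep(1 / 3, 3L),
                 ref_a = detection$area, ref_i = detection$mean_intensity),
            class = "imm_state")
}

#' @keywords internal
ensure_pd <- function(P) {
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    P <- P + diag(nrow(P)) * (abs(min(ev)) + 1e-9)
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance not positive-definite after jitter")
  }
  P
}

#' IMM mixing and one-frame prediction
#'
#' Standard IMM interaction: model states are mixed with transition-weighted
#' probabilities, each model is propagated one frame, and the probability-
#' weighted combined measurement prediction and innovation covariance are
#' returned.
#'
#' @param state an `imm_state` ([imm_init()]).
#' @param params a [link_params()].
#' @return an `imm_prediction`: per-model predicted states (`models`), mixed
#'   model probabilities (`cbar`), combined predicted measurement `pred`
#'   (x, y, area, intensity) and its innovation covariance `S` (4 x 4).
#' @export
imm_predict <- function(state, params) {
  mm <- imm_model_matrices()
  nz <- imm_noise(params, state$ref_a, state$ref_i)
  trans <- params$transition
  mu <- state$mu
  cbar <- as.vector(t(trans) %*% mu)
  cbar <- pmax(cbar, 1e-12); cbar <- cbar / sum(cbar)
  nm <- c("rw", "cv", "ca")
  xp <- vector("list", 3L); Pp <- vector("list", 3L)
  for (j in 1:3) {
    # mixing probabilities mu_{i|j}; a model unreachable under the current
    # probabilities keeps its own state
    denom <- sum(trans[, j] * mu)
    mij <- if (denom > 1e-300) {
      trans[, j] * mu / denom
    } else {
      as.numeric(seq_len(3) == j)
    }
    x_mix <- Reduce(`+`, lapply(1:3, function(i) mij[i] * state$x[[i]]))
    P_mix <- Reduce(`+`, lapply(1:3, function(i) {
      d <- state$x[[i]] - x_mix
      mij[i] * (state$P[[i]] + tcrossprod(d))
    }))
    Fj <- mm$F[[j]]
    xp[[j]] <- as.vector(Fj %*% x_mix)
    Pp[[j]] <- ensure_pd(Fj %*% P_mix %*% t(Fj) + nz$Q[[nm[j]]])
  }
  H <- mm$H
  zp <- lapply(xp, function(x) as.vector(H %*% x))
  z_comb <- Reduce(`+`, lapply(1:3, function(j) cbar[j] * zp[[j]]))
  S_comb <- Reduce(`+`, lapply(1:3, function(j) {
    d <- zp[[j]] - z_comb
    cbar[j] * (H %*% Pp[[j]] %*% t(H) + nz$R + tcrossprod(d))
  }))
  structure(list(models = list(x = xp, P = Pp), cbar = cbar,
                 pred = z_comb, S = ensure_pd(S_comb),
                 ref_a = state$ref_a, ref_i = state$ref_i),
            class = "imm_prediction")
}

#' Association cost between a prediction and a detection
#'
#' Mahalanobis distance of the positional innovation under the combined
#' innovation covariance, plus `lambda` times the relative area and mean-
#' intensity differences. Detections beyond `max_dist` (Euclidean) are gated
#' to `Inf`.
#'
#' @param prediction an `imm_prediction` ([imm_predict()]).
#' @param detection one-row detection.
#' @param params a [link_params()].
#' @return non-negative scalar cost (possibly `Inf`).
#' @export
association_cost <- function(prediction, detection, params) {
  dx <- detection$x - prediction$pred[1L]
  dy <- detection$y - prediction$pred[2L]
  d <- sqrt(dx^2 + dy^2)
  if (d > params$max_dist) return(Inf)
  Spos <- prediction$S[1:2, 1:2]
  maha <- sqrt(drop(t(c(dx, dy)) %*% solve(Spos, c(dx, dy))))
  morph <- 0
  if (params$lambda > 0) {
    ma <- (detection$area + prediction$pred[3L]) / 2
    mi <- (detection$mean_intensity + prediction$pred[4L]) / 2
    morph <- abs(detection$area - prediction$pred[3L]) / max(ma, 1e-12) +
      abs(detection$mean_intensity - prediction$pred[4L]) / max(mi, 1e-12)
  }
  maha + params$lambda * morph
}

#' Associate predictions with detections
#'
#' Optimal linear-sum assignment on the gated cost matrix, with per-track
#' and per-detection skip options priced at the cost of a displacement of
#' the gate radius (so a pairing is accepted only when cheaper than leaving
#' both sides unmatched).
#'
#' @param predictions list of `imm_prediction` objects.
#' @param detections a detections data.frame for one frame.
#' @param params a [link_params()].
#' @return list with `match` (per-prediction detection row index or `NA`),
#'   `unmatched_tracks`, `unmatched_detections`.
#' @export
assign_detections <- function(predictions, detections, params) {
  n <- length(predictions); m <- nrow(detections)
  if (n == 0L || m == 0L) {
    return(list(match = rep(NA_integer_, n),
                unmatched_tracks = seq_len(n),
                unmatched_detections = seq_len(m)))
  }
  cost <- matrix(Inf, n, m)
  sd_eff <- numeric(n)
  for (i in seq_len(n)) {
    p <- predictions[[i]]
    Spos <- p$S[1:2, 1:2]
    sd_eff[i] <- sqrt(mean(diag(Spos)))
    dx <- detections$x - p$pred[1L]
    dy <- detections$y - p$pred[2L]
    within <- which(dx^2 + dy^2 <= params$max_dist^2)
    for (j in within) {
      cost[i, j] <- association_cost(p, detections[j, , drop = FALSE], params)
    }
  }
  skip <- params$max_dist / stats::median(sd_eff)
  match <- gated_assignment(cost, skip)
  list(match = match,
       unmatched_tracks = which(is.na(match)),
       unmatched_detections = setdiff(seq_len(m), match[!is.na(match)]))
}

#' Per-model Kalman update and model-probability update
#'
#' Updates every model filter with the assigned measurement and re-weights
#' the model probabilities by their Gaussian innovation likelihoods.
#'
#' @param state the `imm_state` that produced `prediction`.
#' @param prediction the matching `imm_prediction`.
#' @param detection the assigned one-row detection.
#' @param params a [link_params()].
#' @return the updated `imm_state`.
#' @export
imm_update <- function(state, prediction, detection, params) {
  mm <- imm_model_matrices()
  nz <- imm_noise(params, state$ref_a, state$ref_i)
  H <- mm$H
  z <- c(detection$x, detection$y, detection$area, detection$mean_intensity)
  lik <- numeric(3L)
  for (j in 1:3) {
    xp <- prediction$models$x[[j]]
    Pp <- prediction$models$P[[j]]
    Sj <- H %*% Pp %*% t(H) + nz$R
    Sj <- (Sj + t(Sj)) / 2
    innov <- z - as.vector(H %*% xp)
    Sinv <- solve(Sj)
    K <- Pp %*% t(H) %*% Sinv
    state$x[[j]] <- xp + as.vector(K %*% innov)
    P <- (diag(8L) - K %*% H) %*% Pp
    state$P[[j]] <- (P + t(P)) / 2
    md2 <- drop(t(innov) %*% Sinv %*% innov)
    lik[j] <- exp(-0.5 * md2) / sqrt((2 * pi)^4 * det(Sj))
  }
  mu <- prediction$cbar * (lik + 1e-300)
  state$mu <- mu / sum(mu)
  state
}

#' @keywords internal
coast_state <- function(state, prediction) {
  state$x <- prediction$models$x
  state$P <- prediction$models$P
  state$mu <- prediction$cbar
  state
}

#' Link per-frame detections into trajectories
#'
#' Frame-by-frame IMM predict / associate / update. Unmatched tracks coast on
#' their predicted state for up to `max_gap` frames (coasted points are
#' flagged interpolated) and then terminate; unmatched detections start new
#' tracks. Tracks with fewer than `min_length` real detections are dropped.
#'
#' @param detections a `detections` data.frame covering all frames, or a list
#'   of per-frame detection tables.
#' @param params a [link_params()].
#' @return a `tracks` data.frame: `track_id, frame, x, y, interpolated, area,
#'   mean_intensity, model_rw, model_cv, model_ca`.
#' @export
link_tracks <- function(detections, params = link_params()) {
  if (is.data.frame(detections)) {
    if (nrow(detections) == 0L) return(empty_tracks())
    frames <- seq(min(detections$frame), max(detections$frame))
    det_list <- lapply(frames, function(t) {
      detections[detections$frame == t, , drop = FALSE]
    })
  } else {
    det_list <- detections
    frames <- seq_along(det_list)
  }
  if (length(det_list) < 2L) stop("linking requires at least 2 frames")
  active <- list()   # each: list(id, state, gaps, n_real, rows)
  done <- list()
  next_id <- 1L
  start_track <- function(det, t) {
    tr <- list(id = next_id, state = imm_init(det, params), gaps = 0L,
               n_real = 1L,
               rows = list(track_row(next_id, t, det$x, det$y, FALSE,
                                     det$area, det$mean_intensity,
                                     rep(1 / 3, 3L))))
    next_id <<- next_id + 1L
    tr
  }
  t1 <- frames[1L]
  d1 <- det_list[[1L]]
  for (j in seq_len(nrow(d1))) {
    active[[length(active) + 1L]] <- start_track(d1[j, , drop = FALSE], t1)
  }
  for (ti in seq_along(frames)[-1L]) {
    t <- frames[ti]
    dets <- det_list[[ti]]
    preds <- lapply(active, function(tr) imm_predict(tr$state, params))
    asg <- assign_detections(preds, dets, params)
    new_active <- list()
    for (i in seq_along(active)) {
      tr <- active[[i]]
      j <- asg$match[i]
      if (!is.na(j)) {
        det <- dets[j, , drop = FALSE]
        tr$state <- imm_update(tr$state, preds[[i]], det, params)
        tr$gaps <- 0L
        tr$n_real <- tr$n_real + 1L
        tr$rows[[length(tr$rows) + 1L]] <-
          track_row(tr$id, t, det$x, det$y, FALSE, det$area,
                    det$mean_intensity, tr$state$mu)
        new_active[[length(new_active) + 1L]] <- tr
      } else {
        tr$gaps <- tr$gaps + 1L
        if (tr$gaps > params$max_gap) {
          done[[length(done) + 1L]] <- tr
        } else {
          p <- preds[[i]]
          tr$state <- coast_state(tr$state, p)
          tr$rows[[length(tr$rows) + 1L]] <-
            track_row(tr$id, t, p$pred[1L], p$pred[2L], TRUE, p$pred[3L],
                      p$pred[4L], p$cbar)
          new_active[[length(new_active) + 1L]] <- tr
        }
      }
    }
    for (j in asg$unmatched_detections) {
      new_active[[length(new_active) + 1L]] <-
        start_track(dets[j, , drop = FALSE], t)
    }
    active <- new_active
  }
  done <- c(done, active)
  out <- list()
  for (tr in done) {
    if (tr$n_real < params$min_length) next
    rows <- do.call(rbind, tr$rows)
    # trailing coasted points are artefacts of termination, not gaps
    while (nrow(rows) > 0L && rows$interpolated[nrow(rows)]) {
      rows <- rows[-nrow(rows), , drop = FALSE]
    }
    out[[length(out) + 1L]] <- rows
  }
  if (length(out) == 0L) return(empty_tracks())
  res <- do.call(rbind, out)
  # renumber ids consecutively in order of first appearance
  res$track_id <- match(res$track_id, unique(res$track_id))
  res <- res[order(res$track_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tracks", "data.frame")
  attr(res, "params") <- params
  res
}

#' @keywords internal
track_row <- function(id, frame, x, y, interp, area, intensity, mu) {
  data.frame(track_id = id, frame = frame, x = x, y = y,
             interpolated = interp, area = area, mean_intensity = intensity,
             model_rw = mu[1L], model_cv = mu[2L], model_ca = mu[3L])
}

#' @keywords internal
empty_tracks <- function() {
  res <- data.frame(track_id = integer(0), frame = integer(0),
                    x = numeric(0), y = numeric(0),
                    interpolated = logical(0), area = numeric(0),
                    mean_intensity = numeric(0), model_rw = numeric(0),
                    model_cv = numeric(0), model_ca = numeric(0))
  class(res) <- c("tracks", "data.frame")
  res
}

#' @export
print.tracks <- function(x, ...) {
  n <- length(unique(x$track_id))
  cat(sprintf("tracks: %d trajectory(ies), %d points over %s frames\n",
              n, nrow(x),
              if (nrow(x) > 0L) diff(range(x$frame)) + 1L else 0L))
  if (n > 0L) {
    len <- table(x$track_id)
    cat(sprintf("  length: median %d, range [%d, %d]\n",
                as.integer(stats::median(len)), min(len), max(len)))
  }
  invisible(x)
}
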