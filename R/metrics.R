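# Evaluation of tracking results against ground truth: detection-level
# TPR / FPR / localization RMSE / Jaccard similarity, and track-level
# error and Jaccard similarity with a completeness threshold.

#' Matching specification
#'
#' @param radius match radius in pixels; a detection and a truth position
#'   can only be paired when closer than this. The default for a typical
#'   particle area S is `2 * sqrt(S / pi)` (twice the equivalent-disc
#'   radius).
#' @param theta track completeness threshold for the track-level Jaccard
#'   similarity (fraction of truth time steps that must be matched).
#' @return an object of class `matching_spec`.
#' @export
matching_spec <- function(radius = 2 * sqrt(12 / pi), theta = 0.8) {
  stopifnot(radius > 0, theta > 0, theta <= 1)
  structure(list(radius = radius, theta = theta), class = "matching_spec")
}

#' Match detections to ground-truth positions frame by frame
#'
#' Per frame, an optimal one-to-one assignment that maximises the number of
#' pairs within the match radius and, among those, minimises the total
#' distance. Unmatched estimates are false positives, unmatched truth
#' positions false negatives.
#'
#' @param estimated data.frame with columns `frame, x, y` (detections or
#'   track points).
#' @param truth data.frame with columns `frame, x, y`.
#' @param spec a [matching_spec()].
#' @return list with `tp`, `fp`, `fn` counts, per-pair distances `dist`, and
#'   a per-frame list `pairs` of matched (estimated row, truth row) indices.
#' @export
match_detections <- function(estimated, truth, spec = matching_spec()) {
  frames <- sort(unique(c(estimated$frame, truth$frame)))
  tp <- 0L; fp <- 0L; fn <- 0L
  dists <- numeric(0)
  pairs <- list()
  # skip penalty far above any admissible distance: matches are maximised
  # first, total distance second
  P <- spec$radius * 1e6
  for (t in frames) {
    ei <- which(estimated$frame == t)
    gi <- which(truth$frame == t)
    if (length(ei) == 0L) {
      fn <- fn + length(gi)
      next
    }
    if (length(gi) == 0L) {
      fp <- fp + length(ei)
      next
    }
    dx <- outer(estimated$x[ei], truth$x[gi], "-")
    dy <- outer(estimated$y[ei], truth$y[gi], "-")
    d <- sqrt(dx^2 + dy^2)
    cost <- d
    cost[d > spec$radius] <- Inf
    m <- gated_assignment(cost, P)
    ok <- which(!is.na(m))
    tp <- tp + length(ok)
    fp <- fp + length(ei) - length(ok)
    fn <- fn + length(gi) - length(ok)
    if (length(ok) > 0L) {
      dists <- c(dists, d[cbind(ok, m[ok])])
      pairs[[as.character(t)]] <- cbind(est = ei[ok], truth = gi[m[ok]])
    }
  }
  list(tp = tp, fp = fp, fn = fn, dist = dists, pairs = pairs)
}

#' Detection rates
#'
#' TPR = TP / (TP + FN): fraction of true particles detected.
#' FPR = FP / (TP + FP): fraction of reported detections that are false
#' (defined as 0 when nothing was detected).
#'
#' @param matches output of [match_detections()].
#' @return named numeric vector `c(tpr, fpr)`.
#' @export
detection_rates <- function(matches) {
  tpr <- if (matches$tp + matches$fn == 0L) NA_real_ else
    matches$tp / (matches$tp + matches$fn)
  fpr <- if (matches$tp + matches$fp == 0L) 0 else
    matches$fp / (matches$tp + matches$fp)
  c(tpr = tpr, fpr = fpr)
}

#' Localization RMSE of true-positive detections
#'
#' @param matches output of [match_detections()].
#' @return root mean squared Euclidean error in pixels (`NA` with zero TPs).
#' @export
localization_rmse <- function(matches) {
  if (length(matches$dist) == 0L) return(NA_real_)
  sqrt(mean(matches$dist^2))
}

# per (truth track, estimated track) pair: number of truth time steps whose
# estimated position at the same frame lies within the radius
#' @keywords internal
track_step_counts <- function(est, truth, radius) {
  tids <- unique(truth$track_id)
  eids <- unique(est$track_id)
  counts <- matrix(0L, length(tids), length(eids),
                   dimnames = list(tids, eids))
  esplit <- split(est, est$track_id)
  for (i in seq_along(tids)) {
    g <- truth[truth$track_id == tids[i], , drop = FALSE]
    for (j in seq_along(eids)) {
      e <- esplit[[as.character(eids[j])]]
      k <- match(g$frame, e$frame)
      ok <- !is.na(k)
      if (!any(ok)) next
      d2 <- (g$x[ok] - e$x[k[ok]])^2 + (g$y[ok] - e$y[k[ok]])^2
      counts[i, j] <- sum(d2 <= radius^2)
    }
  }
  counts
}

# one-to-one pairing of truth to estimated tracks maximising the summed
# per-truth-track matched-step fraction
#' @keywords internal
pair_tracks <- function(est, truth, radius) {
  tids <- unique(truth$track_id)
  y_total <- as.integer(table(truth$track_id)[as.character(tids)])
  if (nrow(est) == 0L) {
    return(list(tids = tids, y_total = y_total,
                y_tracked = rep(0L, length(tids)),
                pair = rep(NA_integer_, length(tids)), counts = NULL))
  }
  counts <- track_step_counts(est, truth, radius)
  frac <- counts / y_total
  cost <- -frac
  cost[counts == 0L] <- Inf # pairing with zero overlap = unpaired
  m <- gated_assignment(cost, 0)
  y_tracked <- integer(length(tids))
  ok <- !is.na(m)
  y_tracked[ok] <- counts[cbind(which(ok), m[ok])]
  list(tids = tids, y_total = y_total, y_tracked = y_tracked, pair = m,
       counts = counts)
}

#' Track-based error
#'
#' `E*track = 1 - (sum_i Y_tracked,i / Y_i) / T_total`, where `T_total` is
#' the number of ground-truth tracks, `Y_i` the number of time steps of
#' truth track i and `Y_tracked,i` the number of those steps at which its
#' (one-to-one optimally) paired estimated track lies within the match
#' radius. 0 means every truth time step is tracked; 1 means none is.
#'
#' @param est estimated tracks (`track_id, frame, x, y`).
#' @param truth ground-truth tracks (same columns).
#' @param spec a [matching_spec()].
#' @return scalar in [0, 1].
#' @export
track_error <- function(est, truth, spec = matching_spec()) {
  stopifnot(nrow(truth) > 0L)
  pr <- pair_tracks(est, truth, spec$radius)
  1 - sum(pr$y_tracked / pr$y_total) / length(pr$tids)
}

#' Detection-level Jaccard similarity
#'
#' `JSC = TP / (TP + FP + FN)` over all frames.
#'
#' @param matches output of [match_detections()].
#' @return scalar in [0, 1].
#' @export
jsc_detections <- function(matches) {
  den <- matches$tp + matches$fp + matches$fn
  if (den == 0L) return(NA_real_)
  matches$tp / den
}

#' Track-level Jaccard similarity
#'
#' An estimated track is a true positive when its (one-to-one) paired truth
#' track has a matched-step fraction of at least `spec$theta`; other
#' estimated tracks are false positives and unrecovered truth tracks false
#' negatives. `JSC_theta = TP / (TP + FP + FN)`.
#'
#' @inheritParams track_error
#' @return scalar in [0, 1].
#' @export
jsc_tracks <- function(est, truth, spec = matching_spec()) {
  stopifnot(nrow(truth) > 0L)
  pr <- pair_tracks(est, truth, spec$radius)
  n_est <- length(unique(est$track_id))
  tp <- sum(pr$y_tracked / pr$y_total >= spec$theta)
  fp <- n_est - tp
  fn <- length(pr$tids) - tp
  tp / (tp + fp + fn)
}

#' Evaluate a tracking result against ground truth
#'
#' Computes all supported metrics in one pass: TPR, FPR, localization RMSE,
#' track-based error, and the detection- and track-level Jaccard
#' similarities, along with the underlying counts.
#'
#' @param est estimated tracks or detections (`frame, x, y`, plus
#'   `track_id` for the track-level metrics).
#' @param truth ground truth in the same layout.
#' @param spec a [matching_spec()].
#' @return an object of class `metrics_report`.
#' @export
evaluate_tracking <- function(est, truth, spec = matching_spec()) {
  m <- match_detections(est, truth, spec)
  rates <- detection_rates(m)
  rep <- list(
    tpr = unname(rates["tpr"]), fpr = unname(rates["fpr"]),
    rmse = localization_rmse(m),
    jsc = jsc_detections(m),
    counts = list(tp = m$tp, fp = m$fp, fn = m$fn),
    radius = spec$radius, theta = spec$theta)
  if ("track_id" %in% names(est) && "track_id" %in% names(truth) &&
      nrow(truth) > 0L) {
    rep$e_track <- track_error(est, truth, spec)
    rep$jsc_theta <- jsc_tracks(est, truth, spec)
    rep$n_tracks_est <- length(unique(est$track_id))
    rep$n_tracks_truth <- length(unique(truth$track_id))
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("tracking evaluation\n")
  cat(sprintf("  TPR  %.4f   FPR  %.4f   RMSE %.4f px\n",
              x$tpr, x$fpr, x$rmse))
  cat(sprintf("  JSC  %.4f", x$jsc))
  if (!is.null(x$jsc_theta)) {
    cat(sprintf("   JSC_theta %.4f   E*track %.4f", x$jsc_theta, x$e_track))
  }
  cat("\n")
  cat(sprintf("  TP %d  FP %d  FN %d  (radius %.2f px)\n",
              x$counts$tp, x$counts$fp, x$counts$fn, x$radius))
  invisible(x)
}
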