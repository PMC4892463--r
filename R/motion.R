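# Trajectory kinetics: per-step direction of motion (theta1), direction
# switching between consecutive steps (theta2), rose-diagram histograms and
# track-density images.

#' @keywords internal
split_tracks <- function(tracks, drop_interpolated = TRUE) {
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(tracks)))
  if (drop_interpolated && "interpolated" %in% names(tracks)) {
    tracks <- tracks[!tracks$interpolated, , drop = FALSE]
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  split(tracks, tracks$track_id)
}

#' Per-step direction of motion
#'
#' For each consecutive pair of track points, the direction of the
#' displacement `theta1 = atan2(dy, dx)` mapped to [0, 360) degrees and the
#' Euclidean step length in pixels. Gap-filled (interpolated) points are
#' excluded by default; zero-length steps are excluded and their count
#' reported in the `"n_zero"` attribute.
#'
#' @param tracks a tracks data.frame (`track_id, frame, x, y`, optional
#'   `interpolated`).
#' @param drop_interpolated exclude gap-filled points.
#' @return data.frame `track_id, theta1, length` with attribute `n_zero`.
#' @export
step_angles <- function(tracks, drop_interpolated = TRUE) {
  parts <- split_tracks(tracks, drop_interpolated)
  out <- vector("list", length(parts))
  n_zero <- 0L
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (nrow(p) < 2L) next
    dx <- diff(p$x); dy <- diff(p$y)
    len <- sqrt(dx^2 + dy^2)
    nz <- len > 0
    n_zero <- n_zero + sum(!nz)
    if (!any(nz)) next
    th <- (atan2(dy[nz], dx[nz]) * 180 / pi) %% 360
    out[[k]] <- data.frame(track_id = p$track_id[1L], theta1 = th,
                           length = len[nz])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(track_id = integer(0), theta1 = numeric(0),
                      length = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "n_zero") <- n_zero
  res
}

#' Direction-switching angle between consecutive steps
#'
#' The angle between consecutive displacement vectors: 0 degrees means the
#' particle keeps its direction, 180 degrees a full reversal (the signature
#' of motion caged in a nanodomain). By default the angle is unsigned in
#' [0, 180]; with `signed = TRUE` it is signed in (-180, 180] (positive =
#' counter-clockwise turn). Zero-length steps are skipped.
#'
#' @inheritParams step_angles
#' @param signed return signed turning angles.
#' @return data.frame `track_id, theta2`.
#' @export
switch_angles <- function(tracks, signed = FALSE, drop_interpolated = TRUE) {
  parts <- split_tracks(tracks, drop_interpolated)
  out <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (nrow(p) < 3L) next
    dx <- diff(p$x); dy <- diff(p$y)
    len <- sqrt(dx^2 + dy^2)
    nz <- len > 0
    dx <- dx[nz]; dy <- dy[nz]
    if (length(dx) < 2L) next
    a1 <- atan2(dy[-length(dy)], dx[-length(dx)])
    a2 <- atan2(dy[-1L], dx[-1L])
    d <- (a2 - a1) * 180 / pi
    d <- ((d + 180) %% 360) - 180 # signed in (-180, 180]
    d[d == -180] <- 180
    if (!signed) d <- abs(d)
    out[[k]] <- data.frame(track_id = p$track_id[1L], theta2 = d)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(track_id = integer(0), theta2 = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Rose-diagram histogram
#'
#' 2D angular histogram of (angle, step length): right-open angle bins
#' partitioning the domain, and length bins given by `length_breaks`
#' (lengths beyond the last edge are clipped into the last bin). The counts
#' sum to the number of steps histogrammed.
#'
#' @param angles vector of angles in degrees.
#' @param lengths optional vector of step lengths (same length as `angles`);
#'   omitted = a single length bin.
#' @param n_angle_bins number of angle bins (>= 4); the default gives
#'   10-degree bins (36 bins on [0, 360), 18 on [0, 180]).
#' @param length_breaks length bin edges in pixels (default 5 bins up to the
#'   observed maximum).
#' @param domain angular domain, `c(0, 360)` for theta1 or `c(0, 180)` for
#'   theta2.
#' @return an object of class `rose_histogram`: counts matrix
#'   (angle bin x length bin) plus bin edges.
#' @export
rose_histogram <- function(angles, lengths = NULL, n_angle_bins = NULL,
                           length_breaks = NULL, domain = c(0, 360)) {
  if (is.null(n_angle_bins)) {
    n_angle_bins <- max(4L, as.integer(round((domain[2L] - domain[1L]) / 10)))
  }
  stopifnot(n_angle_bins >= 4L)
  a_edges <- seq(domain[1L], domain[2L], length.out = n_angle_bins + 1L)
  if (is.null(lengths)) lengths <- rep(1, length(angles))
  if (is.null(length_breaks)) {
    top <- if (length(lengths) > 0L) max(lengths) else 1
    if (top <= 0) top <- 1
    length_breaks <- seq(0, top, length.out = 6L)
  }
  nl <- length(length_breaks) - 1L
  counts <- matrix(0L, n_angle_bins, nl)
  if (length(angles) > 0L) {
    a <- pmin(pmax(angles, domain[1L]), domain[2L])
    ai <- findInterval(a, a_edges, rightmost.closed = TRUE)
    ai <- pmin(pmax(ai, 1L), n_angle_bins)
    li <- findInterval(lengths, length_breaks, rightmost.closed = TRUE)
    li <- pmin(pmax(li, 1L), nl) # out-of-range lengths clipped to last bin
    for (k in seq_along(ai)) counts[ai[k], li[k]] <- counts[ai[k], li[k]] + 1L
  }
  structure(list(counts = counts, angle_edges = a_edges,
                 length_edges = length_breaks, domain = domain),
            class = "rose_histogram")
}

#' @export
print.rose_histogram <- function(x, ...) {
  cat(sprintf("rose_histogram: %d angle bins on [%g, %g], %d length bins, %d steps\n",
              nrow(x$counts), x$domain[1L], x$domain[2L], ncol(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' Modal angle bin of a rose histogram
#'
#' @param x a `rose_histogram`.
#' @return centre (degrees) of the angle bin with the highest total count.
#' @export
modal_angle <- function(x) {
  tot <- rowSums(x$counts)
  i <- which.max(tot)
  (x$angle_edges[i] + x$angle_edges[i + 1L]) / 2
}

#' Plot a rose histogram as a polar diagram
#'
#' Petal sections are stacked by length bin; petal area is proportional to
#' the count.
#'
#' @param x a `rose_histogram`.
#' @param col colours, one per length bin.
#' @param main plot title.
#' @param ... unused.
#' @export
plot.rose_histogram <- function(x, col = NULL,
                                main = "rose diagram", ...) {
  nb <- nrow(x$counts); nl <- ncol(x$counts)
  if (is.null(col)) col <- grDevices::hcl.colors(nl, "viridis")
  tot <- rowSums(x$counts)
  rmax <- max(sqrt(tot), 1)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_len(nb)) {
    a1 <- x$angle_edges[i] * pi / 180
    a2 <- x$angle_edges[i + 1L] * pi / 180
    r0 <- 0
    for (l in seq_len(nl)) {
      cnt <- x$counts[i, l]
      if (cnt == 0L) next
      r1 <- sqrt(r0^2 + cnt) # equal-area stacking
      aa <- seq(a1, a2, length.out = 12L)
      graphics::polygon(c(r0 * cos(aa), rev(r1 * cos(aa))),
                        c(r0 * sin(aa), rev(r1 * sin(aa))),
                        col = col[l], border = NA)
      r0 <- r1
    }
  }
  graphics::symbols(0, 0, circles = rmax, inches = FALSE, add = TRUE,
                    fg = "grey50")
  invisible(x)
}

#' @keywords internal
bresenham <- function(r0, c0, r1, c1) {
  # integer line between (r0, c0) and (r1, c1), inclusive
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  rows <- integer(n); cols <- integer(n)
  err <- dc - dr
  r <- r0; c <- c0
  for (k in seq_len(n)) {
    rows[k] <- r; cols[k] <- c
    if (r == r1 && c == c1) {
      rows <- rows[seq_len(k)]; cols <- cols[seq_len(k)]
      break
    }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  cbind(rows, cols)
}

#' Track-density image
#'
#' Per pixel, the number of distinct tracks whose piecewise-linear path
#' (Bresenham rasterization between consecutive points) visits that pixel;
#' a track revisiting a pixel is counted once.
#'
#' @param tracks a tracks data.frame.
#' @param shape image extent `c(height, width)` in pixels.
#' @param drop_interpolated exclude gap-filled points from the path.
#' @return integer matrix of track counts per pixel.
#' @export
track_density <- function(tracks, shape, drop_interpolated = FALSE) {
  h <- shape[1L]; w <- shape[2L]
  dens <- matrix(0L, h, w)
  parts <- split_tracks(tracks, drop_interpolated)
  for (p in parts) {
    rr <- pmin(pmax(round(p$y) + 1L, 1L), h)
    cc <- pmin(pmax(round(p$x) + 1L, 1L), w)
    visited <- matrix(FALSE, h, w)
    if (nrow(p) == 1L) {
      visited[rr, cc] <- TRUE
    } else {
      for (k in seq_len(nrow(p) - 1L)) {
        px <- bresenham(rr[k], cc[k], rr[k + 1L], cc[k + 1L])
        visited[px] <- TRUE
      }
    }
    dens <- dens + visited
  }
  dens
}
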