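# Particle detection: particle probability image (PPI) from multi-scale
# Haar-like contrast features, soft-thresholded particle-existing regions
# (PERs), marker-controlled watershed segmentation, sub-pixel localization,
# and adaptive refinement of the user parameters.

#' Detection parameters
#'
#' The five user parameters of the detector plus the derived particle
#' enhancement factor F.
#'
#' @param S typical particle size: area in pixels.
#' @param s minimum particle size: area in pixels (1 <= s <= S).
#' @param N expected number of particles per frame.
#' @param density particle density class: `"low"`, `"medium"` or `"high"`.
#' @param snr estimated signal-to-noise ratio of the movie.
#' @return an object of class `detection_params` with the derived factor `F`.
#' @export
detection_params <- function(S, s, N, density = c("low", "medium", "high"),
                             snr = 4) {
  density <- match.arg(density)
  stopifnot(s >= 1, S >= s, N >= 1, snr > 0)
  structure(list(S = S, s = s, N = N, density = density, snr = snr,
                 F = enhancement_factor(snr, density)),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "detection_params: S=%g px, s=%g px, N=%g, density=%s, snr=%.2f, F=%.3f\n",
    x$S, x$s, x$N, x$density, x$snr, x$F))
  invisible(x)
}

#' Particle enhancement factor
#'
#' Maps the estimated SNR and density class to the enhancement factor F that
#' scales the particle-pixel budget of the classifier:
#' `F = clamp(1 + 0.25 * max(0, 4 - snr), 1, 3) * mult(density)` with
#' density multipliers 1.0 / 1.25 / 1.5 for low / medium / high. F is
#' non-increasing in SNR and non-decreasing in density.
#'
#' @param snr estimated signal-to-noise ratio (> 0).
#' @param density density class.
#' @return the enhancement factor F (>= 1).
#' @export
enhancement_factor <- function(snr, density = c("low", "medium", "high")) {
  density <- match.arg(density)
  stopifnot(snr > 0)
  base <- min(max(1 + 0.25 * max(0, 4 - snr), 1), 3)
  mult <- c(low = 1.0, medium = 1.25, high = 1.5)[[density]]
  base * mult
}

#' Multi-scale Haar-like contrast features
#'
#' For every pixel, the local contrast between a small inner window centred
#' at the pixel and its immediately surrounding ring (response = inner mean -
#' surround mean), computed for three kernel geometries (centre-surround
#' square, horizontal bar, vertical bar) over a range of spatial scales. The
#' output is the per-pixel maximum over all kernels and scales. Borders are
#' handled by reflection padding; the kernels are DC-free, so a constant
#' offset leaves the features unchanged.
#'
#' Scales are odd inner widths from `odd(sqrt(s))` to `odd(2 * sqrt(S))`; the
#' surround ring width equals the inner half-width (at least 1 pixel).
#'
#' @param frame 2D numeric matrix of grey levels.
#' @param S typical particle area, pixels.
#' @param s minimum particle area, pixels.
#' @return matrix of per-pixel maximal contrast, with the inner widths used
#'   stored in the `"scales"` attribute.
#' @export
compute_haar_features <- function(frame, S, s) {
  stopifnot(is.matrix(frame), all(is.finite(frame)), S >= s, s >= 1)
  nr <- nrow(frame); nc <- ncol(frame)
  # scale bounds round inward: ties go up for the smallest scale (a 1-px
  # inner window is raw pixel noise) and down for the largest
  w_min <- 2L * as.integer(floor(sqrt(s) / 2)) + 1L
  w_max <- max(odd_near(2 * sqrt(S)), w_min)
  widths <- seq.int(w_min, w_max, by = 2L)
  # drop scales whose outer window exceeds the image
  outer_of <- function(w) w + 2L * max(1L, (w - 1L) %/% 2L)
  ok <- vapply(widths, outer_of, integer(1)) <= min(nr, nc)
  if (!all(ok)) {
    warning("skipping ", sum(!ok), " Haar scale(s) larger than the image")
    widths <- widths[ok]
  }
  if (length(widths) == 0L) stop("no usable Haar scale for this image size")
  pmax_pad <- max(vapply(widths, function(w) (outer_of(w) - 1L) %/% 2L, integer(1)))
  ii <- integral_image(pad_reflect(frame, pmax_pad))
  rect_mean <- function(hr, hc) {
    box_sum_padded(ii, nr, nc, hr, hc, pmax_pad) /
      ((2 * hr + 1) * (2 * hc + 1))
  }
  ring_response <- function(ihr, ihc, r) {
    n_in <- (2 * ihr + 1) * (2 * ihc + 1)
    n_out <- (2 * (ihr + r) + 1) * (2 * (ihc + r) + 1)
    inner_sum <- box_sum_padded(ii, nr, nc, ihr, ihc, pmax_pad)
    outer_sum <- box_sum_padded(ii, nr, nc, ihr + r, ihc + r, pmax_pad)
    inner_sum / n_in - (outer_sum - inner_sum) / (n_out - n_in)
  }
  out <- matrix(-Inf, nr, nc)
  for (w in widths) {
    hw <- (w - 1L) %/% 2L
    r <- max(1L, hw)
    out <- pmax(out, ring_response(hw, hw, r)) # centre-surround square
    b <- odd_near(w / 2)
    if (b < w) {
      hb <- (b - 1L) %/% 2L
      out <- pmax(out, ring_response(hb, hw, r)) # horizontal bar
      out <- pmax(out, ring_response(hw, hb, r)) # vertical bar
    }
  }
  attr(out, "scales") <- widths
  out
}

#' Classify pixels into particle and background
#'
#' The K pixels with the highest Haar feature value are labelled particle,
#' with `K = round(F * N * S)` capped at 25% of the image; ties are broken in
#' raster order (row-major, top-left first).
#'
#' @param haar Haar feature image ([compute_haar_features()]).
#' @param params a [detection_params()] object.
#' @return logical matrix, `TRUE` = particle pixel.
#' @export
classify_pixels <- function(haar, params) {
  nr <- nrow(haar); nc <- ncol(haar)
  npx <- nr * nc
  K <- as.integer(round(params$F * params$N * params$S))
  if (K >= npx) {
    stop("particle-pixel budget K = ", K,
         " not smaller than the image (", npx, " px); ",
         "parameters are inconsistent with the image size")
  }
  K <- min(K, as.integer(floor(0.25 * npx)))
  out <- matrix(FALSE, nr, nc)
  if (K <= 0L) return(out)
  v <- as.vector(t(haar)) # raster (row-major) order
  ord <- order(-v, seq_along(v), method = "radix")
  sel <- ord[seq_len(K)]
  rows <- (sel - 1L) %/% nc + 1L
  cols <- (sel - 1L) %% nc + 1L
  out[cbind(rows, cols)] <- TRUE
  out
}

#' Particle probability image
#'
#' PPI(p) = fraction of classified particle pixels within the w x w window
#' centred at p, where w is the nearest odd integer to `sqrt(S)`. Windows at
#' the border use their intersection with the image and its actual pixel
#' count, so every value lies in [0, 1].
#'
#' @param binary logical particle/background map ([classify_pixels()]).
#' @param S typical particle area, pixels.
#' @return numeric matrix of particle probabilities in [0, 1].
#' @export
compute_ppi <- function(binary, S) {
  nr <- nrow(binary); nc <- ncol(binary)
  h <- (odd_near(sqrt(S)) - 1L) %/% 2L
  ii <- integral_image(binary * 1)
  r <- seq_len(nr); c <- seq_len(nc)
  r1 <- pmax(r - h, 1L); r2 <- pmin(r + h, nr)
  c1 <- pmax(c - h, 1L); c2 <- pmin(c + h, nc)
  counts <- ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
    ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  denom <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  counts / denom
}

#' Extract particle existing regions (PERs)
#'
#' Initial mask: `PPI >= 1/e`, labelled with 8-connectivity. Soft, region-
#' local refinement: within each region the threshold is raised to
#' `max(1/e, 0.5 * max PPI of the region)`, the surviving pixels are
#' relabelled, and regions smaller than `s` pixels are discarded.
#'
#' @param ppi particle probability image ([compute_ppi()]).
#' @param s minimum particle area, pixels.
#' @return integer label matrix (0 = background) with the number of regions
#'   in attribute `"n"`.
#' @export
extract_pers <- function(ppi, s = 1) {
  thr0 <- exp(-1)
  mask <- ppi >= thr0
  if (!any(mask)) {
    out <- matrix(0L, nrow(ppi), ncol(ppi))
    attr(out, "n") <- 0L
    return(out)
  }
  lab <- label_components(mask)
  n <- max(lab)
  keep <- matrix(FALSE, nrow(ppi), ncol(ppi))
  reg_max <- vapply(seq_len(n), function(g) max(ppi[lab == g]), numeric(1))
  for (g in seq_len(n)) {
    thr <- max(thr0, 0.5 * reg_max[g])
    keep <- keep | (lab == g & ppi >= thr)
  }
  lab2 <- label_components(keep)
  n2 <- max(lab2)
  if (n2 > 0L && s > 1) {
    sizes <- tabulate(lab2[lab2 > 0L], nbins = n2)
    drop <- which(sizes < s)
    if (length(drop) > 0L) {
      lab2[lab2 %in% drop] <- 0L
      lab2 <- label_components(lab2 > 0L)
    }
  }
  attr(lab2, "n") <- max(lab2)
  lab2
}

#' Find particle markers
#'
#' Markers are strict 8-neighbourhood local maxima of a noise-reduced copy of
#' the raw frame (Gaussian smoothing of sd `sqrt(s / pi)`, the radius of a
#' disc of area `s`) that lie inside a PER and whose PPI exceeds half the
#' maximum PPI of that PER. Equal-valued plateaus collapse to their centroid
#' pixel. A PER with no qualifying maximum falls back to its PPI-maximum
#' pixel (with a warning).
#'
#' @param frame raw 2D grey-level matrix.
#' @param pers PER label matrix ([extract_pers()]).
#' @param ppi particle probability image.
#' @param s minimum particle area, pixels.
#' @return data.frame with columns `row`, `col` (1-based pixel indices) and
#'   `per` (PER id), one row per marker.
#' @export
find_markers <- function(frame, pers, ppi, s) {
  empty <- data.frame(row = integer(0), col = integer(0), per = integer(0))
  n_per <- max(pers)
  if (n_per == 0L) return(empty)
  sigma_g <- sqrt(s / pi)
  sm <- gaussian_smooth(frame, sigma_g)
  mx <- local_maxima(sm)
  res <- empty
  if (nrow(mx) > 0L) {
    per_id <- pers[mx]
    ppi_v <- ppi[mx]
    keep <- per_id > 0L
    mx <- mx[keep, , drop = FALSE]
    per_id <- per_id[keep]; ppi_v <- ppi_v[keep]
    if (nrow(mx) > 0L) {
      per_max <- vapply(seq_len(n_per), function(g) max(ppi[pers == g]), numeric(1))
      keep2 <- ppi_v > 0.5 * per_max[per_id]
      res <- data.frame(row = mx[keep2, 1L], col = mx[keep2, 2L],
                        per = per_id[keep2])
    }
  }
  missing <- setdiff(seq_len(n_per), unique(res$per))
  if (length(missing) > 0L) {
    warning(length(missing), " PER(s) without a qualifying local maximum; ",
            "falling back to the PPI-maximum pixel")
    nr <- nrow(ppi)
    for (g in missing) {
      idx <- which(pers == g)
      # raster-order tie-break on the PPI maximum
      rr <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      o <- order(-ppi[idx], (rr - 1L) * ncol(ppi) + cc)[1L]
      res <- rbind(res, data.frame(row = rr[o], col = cc[o], per = g))
    }
  }
  res[order(res$per, res$row, res$col), , drop = FALSE]
}

#' Marker-controlled watershed segmentation
#'
#' Segments the frame into one region per marker by marker-controlled region
#' growing on the Sobel gradient magnitude of the raw frame, restricted to
#' the PERs (non-PER pixels act as the background marker and are never
#' labelled). Segments are clipped to their marker's PER; segments smaller
#' than `s` pixels are merged into the largest adjacent segment of the same
#' PER, or discarded if there is none.
#'
#' @param frame raw 2D grey-level matrix.
#' @param markers marker table ([find_markers()]).
#' @param pers PER label matrix.
#' @param s minimum particle area, pixels.
#' @return integer label matrix; label k corresponds to marker row k.
#' @export
segment_watershed <- function(frame, markers, pers, s = 1) {
  out <- matrix(0L, nrow(frame), ncol(frame))
  if (nrow(markers) == 0L) return(out)
  if (any(pers[cbind(markers$row, markers$col)] == 0L)) {
    stop("every marker must lie inside a PER")
  }
  grad <- sobel_gradient(frame)
  seeds <- matrix(0L, nrow(frame), ncol(frame))
  seeds[cbind(markers$row, markers$col)] <- seq_len(nrow(markers))
  seg <- EBImage::propagate(grad, seeds, mask = pers > 0L)
  seg <- matrix(as.integer(seg), nrow(frame), ncol(frame))
  # clip each segment to the PER of its marker
  marker_per <- markers$per
  bad <- seg > 0L & pers != matrix(c(0L, marker_per)[seg + 1L], nrow(seg), ncol(seg))
  seg[bad] <- 0L
  # merge undersized segments into the largest adjacent segment in their PER
  if (s > 1) {
    for (pass in 1:5) {
      sizes <- tabulate(seg[seg > 0L], nbins = nrow(markers))
      small <- which(sizes > 0L & sizes < s)
      if (length(small) == 0L) break
      changed <- FALSE
      for (k in small) {
        idx <- which(seg == k)
        nbr <- integer(0)
        nr <- nrow(seg); nc <- ncol(seg)
        rr <- ((idx - 1L) %% nr) + 1L
        cc <- ((idx - 1L) %/% nr) + 1L
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                       c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
          r2 <- rr + d[1L]; c2 <- cc + d[2L]
          okn <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
          nbr <- c(nbr, seg[cbind(r2[okn], c2[okn])])
        }
        nbr <- nbr[nbr > 0L & nbr != k]
        nbr <- nbr[marker_per[nbr] == marker_per[k]]
        if (length(nbr) > 0L) {
          # prefer the largest adjacent segment
          cand <- unique(nbr)
          tgt <- cand[which.max(sizes[cand])]
          seg[idx] <- tgt
        } else {
          seg[idx] <- 0L
        }
        changed <- TRUE
      }
      if (!changed) break
    }
  }
  seg
}

#' @keywords internal
fit_gaussian_2d <- function(patch, x0, y0) {
  # least-squares isotropic 2D Gaussian A*exp(-((x-x0)^2+(y-y0)^2)/(2*sg^2))+b
  # on a small patch; x/y are 0-based coordinates of the patch columns/rows
  nr <- nrow(patch); nc <- ncol(patch)
  xs <- attr(patch, "x"); ys <- attr(patch, "y")
  b0 <- stats::median(patch)
  A0 <- max(patch) - b0
  if (A0 <= 0) return(NULL)
  obj <- function(p) {
    A <- p[1L]; cx <- p[2L]; cy <- p[3L]; lsg <- p[4L]; b <- p[5L]
    sg <- exp(lsg)
    mdl <- b + A * exp(-(outer(rep(1, nr), (xs - cx)^2) +
                           outer((ys - cy)^2, rep(1, nc))) / (2 * sg^2))
    sum((mdl - patch)^2)
  }
  fit <- tryCatch(
    stats::optim(c(A0, x0, y0, log(1), b0), obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  if (p[1L] <= 0 || p[2L] < min(xs) - 1 || p[2L] > max(xs) + 1 ||
      p[3L] < min(ys) - 1 || p[3L] > max(ys) + 1) {
    return(NULL)
  }
  list(x = p[2L], y = p[3L], sigma = exp(p[4L]), amplitude = p[1L], bg = p[5L])
}

#' Sub-pixel particle localization and morphology
#'
#' For typical particle sizes `S >= 9` pixels the position is the background-
#' subtracted intensity-weighted centre of mass of the segment (background =
#' median of the segment's boundary pixels, which doubles as the local clip
#' level and so cancels boundary-truncation bias; negative residuals clipped
#' to 0).
#' For `S < 9` a least-squares isotropic 2D Gaussian is fitted in a 7 x 7
#' window seeded at the marker; on divergence the weighted centroid is used
#' and the detection flagged. Morphology (area, circularity, major/minor
#' axes) and intensity summaries are filled for every detection.
#'
#' @param frame raw 2D grey-level matrix.
#' @param segments segment label matrix ([segment_watershed()]).
#' @param S typical particle area, pixels.
#' @param markers marker table; required for the Gaussian-fit branch.
#' @param frame_index frame number stored on the detections.
#' @param background fixed background level to subtract instead of the
#'   per-segment boundary median (e.g. 0 for pre-subtracted data).
#' @return a `detections` data.frame: `frame, x, y, area, circularity,
#'   major_axis, minor_axis, mean_intensity, peak_intensity, label, fit_fallback`.
#' @export
localize <- function(frame, segments, S, markers = NULL, frame_index = 1L,
                     background = NULL) {
  labs <- sort(unique(segments[segments > 0L]))
  out <- vector("list", length(labs))
  nr <- nrow(frame); nc <- ncol(frame)
  for (j in seq_along(labs)) {
    k <- labs[j]
    idx <- which(segments == k)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    vals <- frame[idx]
    if (is.null(background)) {
      # boundary = segment pixels with a 4-neighbour outside the segment;
      # their median tracks the local clip level, so subtracting it also
      # cancels the asymmetric tail truncation of the segment boundary
      on_bnd <- logical(length(idx))
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- rr + d[1L]; c2 <- cc + d[2L]
        outside <- r2 < 1L | r2 > nr | c2 < 1L | c2 > nc
        inb <- !outside
        nbv <- rep(0L, length(idx))
        nbv[inb] <- segments[cbind(r2[inb], c2[inb])]
        on_bnd <- on_bnd | outside | nbv != k
      }
      bg <- stats::median(vals[on_bnd])
    } else {
      bg <- background
    }
    w <- pmax(vals - bg, 0)
    if (sum(w) == 0) w <- rep(1, length(idx))
    cx <- sum(w * (cc - 1)) / sum(w)
    cy <- sum(w * (rr - 1)) / sum(w)
    fallback <- FALSE
    if (S < 9 && !is.null(markers)) {
      mk <- markers[k, , drop = FALSE] # segment label k is marker row k
      if (nrow(mk) == 1L) {
        r0 <- mk$row; c0 <- mk$col
        rw <- max(1L, r0 - 3L):min(nr, r0 + 3L)
        cw <- max(1L, c0 - 3L):min(nc, c0 + 3L)
        patch <- frame[rw, cw, drop = FALSE]
        attr(patch, "x") <- cw - 1
        attr(patch, "y") <- rw - 1
        fit <- fit_gaussian_2d(patch, c0 - 1, r0 - 1)
        if (!is.null(fit)) {
          cx <- fit$x; cy <- fit$y
        } else {
          fallback <- TRUE
        }
      }
    }
    # keep the centroid inside the segment bounding box
    cx <- min(max(cx, min(cc) - 1), max(cc) - 1)
    cy <- min(max(cy, min(rr) - 1), max(rr) - 1)
    # morphology from the binary segment
    area <- length(idx)
    bmask <- matrix(FALSE, max(rr) - min(rr) + 1L, max(cc) - min(cc) + 1L)
    bmask[cbind(rr - min(rr) + 1L, cc - min(cc) + 1L)] <- TRUE
    perim <- crack_edges(bmask) * pi / 4
    circ <- min(1, 4 * pi * area / perim^2)
    vx <- stats::var(cc) * (area - 1) / area + 1 / 12
    vy <- stats::var(rr) * (area - 1) / area + 1 / 12
    vxy <- if (area > 1) stats::cov(cc, rr) * (area - 1) / area else 0
    if (area == 1L) { vx <- 1 / 12; vy <- 1 / 12 }
    ev <- eigen(matrix(c(vx, vxy, vxy, vy), 2L, 2L), symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    out[[j]] <- data.frame(
      frame = frame_index, x = cx, y = cy, area = area,
      circularity = circ,
      major_axis = 4 * sqrt(ev[1L]), minor_axis = 4 * sqrt(ev[2L]),
      mean_intensity = mean(vals), peak_intensity = max(vals),
      label = k, fit_fallback = fallback)
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else empty_detections()
  class(res) <- c("detections", "data.frame")
  res
}

#' @keywords internal
empty_detections <- function() {
  data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
             area = integer(0), circularity = numeric(0),
             major_axis = numeric(0), minor_axis = numeric(0),
             mean_intensity = numeric(0), peak_intensity = numeric(0),
             label = integer(0), fit_fallback = logical(0))
}

#' Detect particles in a single frame
#'
#' Runs the full detection chain: Haar features, pixel classification, PPI,
#' PER extraction, marker finding, marker-controlled watershed, and
#' localization. Deterministic for fixed inputs.
#'
#' @param frame 2D grey-level matrix.
#' @param params a [detection_params()].
#' @param frame_index frame number stored on the detections.
#' @return a `detections` data.frame (possibly empty).
#' @export
detect_frame <- function(frame, params, frame_index = 1L) {
  haar <- compute_haar_features(frame, params$S, params$s)
  binary <- classify_pixels(haar, params)
  ppi <- compute_ppi(binary, params$S)
  pers <- extract_pers(ppi, params$s)
  if (max(pers) == 0L) return(empty_detections())
  markers <- suppressWarnings(find_markers(frame, pers, ppi, params$s))
  seg <- segment_watershed(frame, markers, pers, params$s)
  localize(frame, seg, params$S, markers = markers, frame_index = frame_index)
}

#' Adaptive parameter refinement
#'
#' Re-runs detection while adjusting the working SNR estimate by bisection
#' over [0.5, 10] until the detected count is within `tolerance` of the
#' expected count N (too few detections lower the SNR estimate, enlarging
#' the enhancement factor F; too many raise it). When the SNR interval is
#' exhausted the density class is stepped instead. Returns the best iterate
#' if the loop does not converge.
#'
#' @param params initial [detection_params()].
#' @param frame 2D grey-level matrix.
#' @param tolerance accepted relative deviation of the detected count from N.
#' @param max_iterations iteration cap.
#' @return list with elements `params` (refined), `detections`, `iterations`
#'   and `converged`.
#' @export
adapt_params <- function(params, frame, tolerance = 0.2, max_iterations = 10L) {
  stopifnot(tolerance > 0, tolerance < 1)
  dens_levels <- c("low", "medium", "high")
  lo <- 0.5; hi <- 10
  snr <- min(max(params$snr, lo), hi)
  dens <- params$density
  best <- NULL; best_dev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    cur <- detection_params(params$S, params$s, params$N, dens, snr)
    det <- detect_frame(frame, cur)
    dev <- abs(nrow(det) - params$N) / params$N
    if (dev < best_dev) {
      best <- list(params = cur, detections = det)
      best_dev <- dev
    }
    if (dev <= tolerance) {
      converged <- TRUE
      break
    }
    if (nrow(det) < params$N) hi <- snr else lo <- snr
    if (hi - lo < 0.1) { # SNR bounds exhausted: step the density class
      di <- match(dens, dens_levels)
      if (nrow(det) < params$N && di < 3L) {
        dens <- dens_levels[di + 1L]
      } else if (nrow(det) > params$N && di > 1L) {
        dens <- dens_levels[di - 1L]
      } else {
        break
      }
      lo <- 0.5; hi <- 10
    }
    snr <- (lo + hi) / 2
  }
  if (!converged) {
    warning("adapt_params did not converge in ", max_iterations,
            " iterations; returning the best iterate")
  }
  list(params = best$params, detections = best$detections,
       iterations = it, converged = converged)
}

#' Detect particles in every frame of a stack
#'
#' Applies [detect_frame()] to each frame. With `carry_n = TRUE` the expected
#' particle count N for frame t+1 is updated to the count detected in frame
#' t. With `adaptive = TRUE` the first frame is processed through
#' [adapt_params()] and the refined parameters are used for the remainder.
#'
#' @param stack a `frame_stack`.
#' @param params a [detection_params()].
#' @param adaptive refine parameters on the first frame.
#' @param carry_n carry the detected count forward as the next frame's N.
#' @param verbose print per-frame progress.
#' @return a `detections` data.frame covering all frames.
#' @export
detect_stack <- function(stack, params, adaptive = FALSE, carry_n = TRUE,
                         verbose = FALSE) {
  out <- vector("list", length(stack$frames))
  p <- params
  for (t in seq_along(stack$frames)) {
    if (t == 1L && adaptive) {
      ad <- adapt_params(p, stack$frames[[t]])
      p <- ad$params
      det <- ad$detections
      det$frame <- t
    } else {
      det <- detect_frame(stack$frames[[t]], p, frame_index = t)
    }
    if (verbose) {
      message(sprintf("frame %d: %d particles", t, nrow(det)))
    }
    out[[t]] <- det
    if (carry_n && nrow(det) >= 1L) {
      p <- detection_params(p$S, p$s, nrow(det), p$density, p$snr)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("detections", "data.frame")
  res
}

#' @export
print.detections <- function(x, ...) {
  cat(sprintf("detections: %d particle(s) over %d frame(s)\n",
              nrow(x), length(unique(x$frame))))
  if (nrow(x) > 0L) {
    cat(sprintf("  mean area %.1f px, mean peak %.1f grey levels\n",
                mean(x$area), mean(x$peak_intensity)))
  }
  invisible(x)
}
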