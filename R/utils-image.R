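# Internal image primitives shared by the detection pipeline.
#
# Images are numeric matrices indexed [row, col]. Coordinates exposed to users
# are 0-based pixel-centre positions with x = column, y = row, so pixel
# [r, c] sits at (x, y) = (c - 1, r - 1).

#' @keywords internal
odd_near <- function(x) {
  # nearest odd integer; ties resolved toward the smaller scale
  k1 <- 2L * as.integer(floor((x - 1) / 2)) + 1L # largest odd <= x (or 1)
  k1 <- pmax(k1, 1L)
  k2 <- k1 + 2L
  ifelse(k2 - x < x - k1, k2, k1)
}

# Reflect-pad a matrix by `p` pixels on every side.
#' @keywords internal
pad_reflect <- function(m, p) {
  if (p == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (p >= nr || p >= nc) stop("padding exceeds image size")
  ridx <- c(rev(seq_len(p) + 1L), seq_len(nr), nr - seq_len(p))
  cidx <- c(rev(seq_len(p) + 1L), seq_len(nc), nc - seq_len(p))
  m[ridx, cidx, drop = FALSE]
}

# Summed-area table with a zero top/left guard row, so rectangle sums are
# ii[r2+1, c2+1] - ii[r1, c2+1] - ii[r2+1, c1] + ii[r1, c1].
#' @keywords internal
integral_image <- function(m) {
  cs <- matrix(apply(m, 2L, cumsum), nrow(m), ncol(m))
  cs <- t(matrix(apply(cs, 1L, cumsum), ncol(m), nrow(m)))
  out <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  out[-1L, -1L] <- cs
  out
}

# Sum of m over a (2*hr+1) x (2*hc+1) window centred at every pixel of the
# unpadded image, where `ii` is the integral image of a reflect-padded copy
# with pad p >= max(hr, hc).
#' @keywords internal
box_sum_padded <- function(ii, nr, nc, hr, hc, p) {
  r <- seq_len(nr) + p
  c <- seq_len(nc) + p
  r1 <- r - hr; r2 <- r + hr
  c1 <- c - hc; c2 <- c + hc
  ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
    ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

# 8-connected labelling of a logical matrix. EBImage::bwlabel is 4-connected,
# so diagonal-touching 4-components are merged with a union-find pass.
#' @keywords internal
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left shifts)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- cbind(c(a1[keep1], a2[keep2]), c(b1[keep1], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- integer(n)
  relab[sort(unique(root))] <- seq_along(unique(root))
  new <- c(0L, relab[root])
  matrix(new[lab + 1L], nr, nc)
}

# Sobel gradient magnitude with reflected borders.
#' @keywords internal
sobel_gradient <- function(m) {
  pm <- pad_reflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) pm[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc, drop = FALSE]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

# Separable Gaussian smoothing with reflected borders (deterministic border
# handling, unlike FFT-based filters).
#' @keywords internal
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- min(rad, min(dim(m)) - 1L)
  if (p < rad) { # tiny image: trim kernel
    rad <- p
    k <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  }
  pm <- pad_reflect(m, rad)
  nr <- nrow(m); nc <- ncol(m)
  # convolve along rows (vertical), then columns
  tmp <- matrix(0, nr, ncol(pm))
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * pm[seq_len(nr) + (i - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[, seq_len(nc) + (i - 1L), drop = FALSE]
  }
  out
}

# Strict 8-neighbourhood local maxima; equal-valued plateau components that
# are regional maxima collapse to the component pixel nearest their centroid.
# Returns a two-column matrix (row, col).
#' @keywords internal
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pm <- pad_reflect(m, 1L)
  pm_max <- matrix(-Inf, nr, nc)
  pm_gt <- matrix(FALSE, nr, nc) # has a strictly greater neighbour
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pm[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc, drop = FALSE]
    pm_gt <- pm_gt | (nb > m)
  }
  cand <- !pm_gt
  if (!any(cand)) return(matrix(integer(0), 0L, 2L))
  lab <- label_components(cand)
  n <- max(lab)
  out <- matrix(0L, n, 2L)
  keep <- logical(n)
  idx <- which(lab > 0L)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ll <- lab[idx]
  for (g in seq_len(n)) {
    sel <- ll == g
    rs <- rr[sel]; cs <- cc[sel]
    # plateau must be constant-valued to be a genuine regional maximum
    if (max(m[cbind(rs, cs)]) - min(m[cbind(rs, cs)]) > 0) next
    mr <- mean(rs); mc <- mean(cs)
    j <- which.min((rs - mr)^2 + (cs - mc)^2)
    out[g, ] <- c(rs[j], cs[j])
    keep[g] <- TRUE
  }
  out[keep, , drop = FALSE]
}

# Count of exposed 4-neighbour pixel edges of a pixel set (crack perimeter).
#' @keywords internal
crack_edges <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pm <- matrix(FALSE, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pm[2:(nr + 1L), 2:(nc + 1L)]
  edges <- 0L
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- pm[2:(nr + 1L) + d[1L], 2:(nc + 1L) + d[2L]]
    edges <- edges + sum(inner & !nb)
  }
  edges
}
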