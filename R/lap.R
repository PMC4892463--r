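# Linear-sum assignment (Jonker-Volgenant style shortest augmenting paths).
# No LAP solver ships with the installed stack, so a compact exact solver is
# provided here and reused by the linker and the evaluation matcher.

#' Solve a rectangular linear-sum assignment problem
#'
#' Finds the assignment of rows to columns minimising total cost. Forbidden
#' pairings are encoded as `Inf`. When `nrow(cost) <= ncol(cost)` every row is
#' assigned; otherwise every column is. An assignment using a forbidden pair
#' is reported as unassigned (`NA`) for that row.
#'
#' @param cost numeric cost matrix; `Inf` forbids a pairing.
#' @return integer vector of length `nrow(cost)`: the column assigned to each
#'   row (`NA` if unassigned).
#' @examples
#' solve_lap(matrix(c(4, 1, 2, 3), 2, 2)) # c(2, 1)
#' @export
solve_lap <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) {
    cost <- t(cost)
    tmp <- n; n <- m; m <- tmp
    transposed <- TRUE
  }
  BIG <- max(cost[is.finite(cost)], 0) * (n + m + 1) + 1
  if (!is.finite(BIG)) BIG <- 1
  a <- cost
  a[!is.finite(a)] <- BIG
  u <- numeric(n)
  v <- numeric(m)
  p <- integer(m + 1L) # p[j+1] = row assigned to column j (0 = free); j = 0 is virtual
  way <- integer(m)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- a[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) - 1L
      rows <- p[usedj + 1L]
      u[rows] <- u[rows] + delta
      v[usedj[usedj > 0L]] <- v[usedj[usedj > 0L]] - delta
      minv[!used[-1L]] <- minv[!used[-1L]] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) {
    if (p[j + 1L] > 0L) assign_row[p[j + 1L]] <- j
  }
  # drop assignments realised through forbidden entries
  for (i in seq_len(n)) {
    if (!is.na(assign_row[i]) && !is.finite(cost[i, assign_row[i]])) {
      assign_row[i] <- NA_integer_
    }
  }
  if (!transposed) return(assign_row)
  out <- rep(NA_integer_, ncol(cost))
  ok <- !is.na(assign_row)
  out[assign_row[ok]] <- which(ok)
  out
}

# Gated assignment with per-row and per-column skip options: match i-j only
# when cheaper (in total) than leaving both unmatched at `skip` each. The
# gate graph is decomposed into connected components so the augmented LAP
# stays small even for dense frames.
#' @keywords internal
gated_assignment <- function(cost, skip) {
  n <- nrow(cost); m <- ncol(cost)
  match_row <- rep(NA_integer_, n)
  if (n == 0L || m == 0L) return(match_row)
  fin <- is.finite(cost)
  rows_active <- which(rowSums(fin) > 0L)
  cols_active <- which(colSums(fin) > 0L)
  if (length(rows_active) == 0L) return(match_row)
  # union-find over rows (1..n) and columns (n+1..n+m)
  parent <- seq_len(n + m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  idx <- which(fin, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    ra <- find(idx[k, 1L]); rb <- find(n + idx[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp_of_row <- vapply(rows_active, find, integer(1))
  comp_of_col <- vapply(n + cols_active, find, integer(1))
  for (comp in unique(comp_of_row)) {
    ri <- rows_active[comp_of_row == comp]
    ci <- cols_active[comp_of_col == comp]
    p <- length(ri); d <- length(ci)
    if (p == 1L && d == 1L) {
      if (cost[ri, ci] <= 2 * skip) match_row[ri] <- ci
      next
    }
    # augmented square problem: skip lanes on the diagonal
    sz <- p + d
    aug <- matrix(Inf, sz, sz)
    aug[seq_len(p), seq_len(d)] <- cost[ri, ci, drop = FALSE]
    aug[cbind(seq_len(p), d + seq_len(p))] <- skip
    aug[cbind(p + seq_len(d), seq_len(d))] <- skip
    aug[p + seq_len(d), d + seq_len(p)] <- 0
    sol <- solve_lap(aug)
    for (a in seq_len(p)) {
      j <- sol[a]
      if (!is.na(j) && j <= d) match_row[ri[a]] <- ci[j]
    }
  }
  match_row
}
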