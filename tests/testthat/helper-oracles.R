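# Brute-force oracles, deliberately naive: per-pixel loops that the
# vectorized / distance-transform implementations must reproduce
# exactly on small fixtures.

# Min Euclidean distance from every pixel center to any TRUE pixel.
brute_dist_to_set <- function(set_bin) {
  idx <- which(set_bin, arr.ind = TRUE)
  out <- matrix(Inf, nrow(set_bin), ncol(set_bin))
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    if (nrow(idx))
      out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
  }
  out
}

# Min distance from every pixel center to any FALSE pixel (background),
# treating pixels beyond the image border as background too.
brute_dist_to_bg <- function(cell_bin) {
  padded <- matrix(FALSE, nrow(cell_bin) + 2L, ncol(cell_bin) + 2L)
  padded[2:(nrow(cell_bin) + 1L), 2:(ncol(cell_bin) + 1L)] <- cell_bin
  d <- brute_dist_to_set(!padded)
  d[2:(nrow(cell_bin) + 1L), 2:(ncol(cell_bin) + 1L)]
}

# 8-connected components by queue-based flood fill.
flood_fill_components <- function(bw) {
  bw <- as.matrix(bw) != 0
  lab <- matrix(0L, nrow(bw), ncol(bw))
  k <- 0L
  for (start in which(bw)) {
    if (lab[start] > 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    nr <- nrow(bw)
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(bw) &&
            bw[rr, cc] && lab[rr, cc] == 0L) {
          j <- (cc - 1L) * nr + rr
          lab[j] <- k
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Do two labelings induce the same partition of the foreground?
same_partition <- function(a, b) {
  fa <- a > 0; fb <- b > 0
  if (!identical(fa, fb)) return(FALSE)
  pa <- split(which(fa), a[fa])
  pb <- split(which(fb), b[fb])
  setequal(lapply(pa, sort), lapply(pb, sort))
}

# Distance from pixel centers to a polyline/vertical edge, by looping
# over pixels and segments with plain point-segment geometry.
brute_edge_dist <- function(nr, nc, edge) {
  seg_dist <- function(px, py, ax, ay, bx, by) {
    vx <- bx - ax; vy <- by - ay
    l2 <- vx^2 + vy^2
    t <- if (l2 == 0) 0 else max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / l2))
    sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2)
  }
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.matrix(edge)) out[r, c] <- abs(c - edge)
    else {
      d <- Inf
      for (i in seq_len(nrow(edge) - 1L))
        d <- min(d, seg_dist(c, r, edge[i, 1], edge[i, 2],
                             edge[i + 1, 1], edge[i + 1, 2]))
      out[r, c] <- d
    }
  }
  out
}

# Random small binary matrix for property tests.
random_binary <- function(nr, nc, p = 0.4) matrix(stats::runif(nr * nc) < p, nr, nc)

meta1 <- function(px = 1) image_meta(px)
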