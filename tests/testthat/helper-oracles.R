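# Independent oracles used across the suite. These deliberately use naive
# double loops / direct formulas, not the package's code paths.

# Brute-force inter-label boundary: pixel (i, j) is a border pixel iff its
# label differs from the pixel below or to the right.
oracle_boundaries <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  b <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i < nr && labels[i, j] != labels[i + 1, j]) b[i, j] <- TRUE
    if (j < nc && labels[i, j] != labels[i, j + 1]) b[i, j] <- TRUE
  }
  b
}

# Exhaustive symmetric mean nearest-neighbour distance between two pixel
# sets (full pairwise distance matrix).
oracle_skeleton_distance <- function(a, b) {
  A <- which(a, arr.ind = TRUE); B <- which(b, arr.ind = TRUE)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

# Independent image-level structure tensor: explicit 2D derivative-of-
# Gaussian kernels applied by direct convolution loops over the interior,
# then eigen() on the summed tensor.
oracle_coherency <- function(frame, gsig = 1, wsig = 4) {
  r <- ceiling(3 * gsig)
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * gsig^2)); g <- g / sum(g)
  d <- -x / gsig^2 * g; d <- d / sum(-d * x)
  kx <- outer(g, d)   # d/d(col)
  kr <- outer(d, g)   # d/d(row)
  nr <- nrow(frame); nc <- ncol(frame)
  margin <- ceiling(3 * wsig) + r
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (i in (margin + 1):(nr - margin)) for (j in (margin + 1):(nc - margin)) {
    patch <- frame[(i - r):(i + r), (j - r):(j + r)]
    gx[i, j] <- sum(patch * kx)
    gy[i, j] <- -sum(patch * kr)
  }
  ri <- (margin + 1):(nr - margin); ci <- (margin + 1):(nc - margin)
  J <- matrix(c(sum(gx[ri, ci]^2), sum(gx[ri, ci] * gy[ri, ci]),
                sum(gx[ri, ci] * gy[ri, ci]), sum(gy[ri, ci]^2)), 2)
  ev <- eigen(J, symmetric = TRUE)
  coh <- (ev$values[1] - ev$values[2]) / sum(ev$values)
  v <- ev$vectors[, 1]  # dominant gradient direction
  dir <- atan2(v[2], v[1]) * 180 / pi + 90   # structure direction
  dir <- (dir + 90) %% 180 - 90
  list(coherency = coh, direction = dir)
}

# Second central moments of a mask by direct summation.
oracle_moments <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  x <- w[, 2] - mean(w[, 2]); y <- -(w[, 1] - mean(w[, 1]))
  J <- matrix(c(mean(x * x), mean(x * y), mean(x * y), mean(y * y)), 2)
  ev <- eigen(J, symmetric = TRUE)
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- (ang + 90) %% 180 - 90
  list(ar = sqrt(ev$values[1] / ev$values[2]), orientation = ang)
}

# SSE of the Kelvin-Voigt model on a log-spaced (D, tau) grid.
oracle_kv_grid_sse <- function(t_s, L_um, n = 200) {
  Ds <- exp(seq(log(max(L_um) / 4), log(max(L_um) * 4), length.out = n))
  taus <- exp(seq(log(max(t_s) / 200), log(max(t_s) * 4), length.out = n))
  best <- Inf
  for (D in Ds) {
    for (tau in taus) {
      sse <- sum((L_um - D * (1 - exp(-t_s / tau)))^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Small straight-line skeleton helpers.
line_skel <- function(nr, nc, col) {
  s <- matrix(FALSE, nr, nc); s[, col] <- TRUE; s
}

disk_mask <- function(n, cx, cy, r) {
  outer(seq_len(n), seq_len(n), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}
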