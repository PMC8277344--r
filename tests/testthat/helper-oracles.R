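# Brute-force oracles, independent of the package implementation.

# Flood fill of {img <= threshold} containing the seed (0-based), plain BFS
# over an explicit queue in R.
flood_fill_oracle <- function(img, seed, threshold, connectivity = 4) {
  H <- nrow(img); W <- ncol(img)
  mask <- matrix(FALSE, H, W)
  if (img[seed[1] + 1, seed[2] + 1] > threshold) return(mask)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  queue <- list(seed + 1)  # 1-based internally
  mask[seed[1] + 1, seed[2] + 1] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (o in offs) {
      r <- p[1] + o[1]; c <- p[2] + o[2]
      if (r < 1 || r > H || c < 1 || c > W) next
      if (mask[r, c] || img[r, c] > threshold) next
      mask[r, c] <- TRUE
      queue <- c(queue, list(c(r, c)))
    }
  }
  mask
}

# Perimeter as an explicit loop over every pixel's 4 unit edges.
edge_length_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  total <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c]) next
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > H || cc < 1 || cc > W || !mask[rr, cc])
        total <- total + 1L
    }
  }
  total
}

# Rasterize per-frame glottal areas directly from the half-width formula:
# row y is open on (c - wL, c) to the left and (c, c + wR) to the right of
# the continuous midline coordinate c = midline_col - 0.5.
glottis_area_oracle <- function(p, k) {
  t <- k / p$fps
  top <- p$glottis_span[1]; bot <- p$glottis_span[2]
  cmid <- p$midline_col - 0.5
  oscL <- p$closure_left +
    p$amp_left * (1 + sin(2 * pi * p$f0 * t + p$phase_left)) / 2
  oscR <- p$closure_right +
    p$amp_right * (1 + sin(2 * pi * p$f0 * t + p$phase_right)) / 2
  left <- 0L; right <- 0L
  for (y in 0:(p$image_height - 1)) {
    m <- if (y >= top && y <= bot) sin(pi * (y - top) / (bot - top)) else 0
    for (x in 0:(p$image_width - 1)) {
      if (x > cmid - m * oscL && x < cmid) left <- left + 1L
      if (x < cmid + m * oscR && x > cmid) right <- right + 1L
    }
  }
  c(left = left, right = right)
}

# Small deterministic healthy clip used by several tests.
tiny_healthy <- function(...) {
  glottis_preset("healthy", duration = 0.1, noise_sigma = 0, ...)
}
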