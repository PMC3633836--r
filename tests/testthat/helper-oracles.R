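# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own code paths: the Otsu oracle
# scans all 256 candidate thresholds on the raw pixel vector, and the depth
# oracle computes all-pairs nearest-background Euclidean distances.

# Exhaustive Otsu: first threshold t (0..255) maximizing between-class
# variance of the split {x <= t} / {x > t}.
brute_otsu <- function(x) {
  bins <- pmin(pmax(round(as.numeric(x)), 0), 255)
  best_t <- NA_integer_; best_v <- -Inf
  n <- length(bins)
  for (t in 0:255) {
    g0 <- bins[bins <= t]; g1 <- bins[bins > t]
    if (length(g0) == 0L || length(g1) == 0L) next
    v <- (length(g0) / n) * (length(g1) / n) * (mean(g0) - mean(g1))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# All-pairs nearest-background Euclidean depth; pixels beyond the frame
# count as background (one padding ring suffices for exact distances).
brute_depth <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pm <- matrix(FALSE, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- mask
  fg <- which(pm, arr.ind = TRUE)
  bg <- which(!pm, arr.ind = TRUE)
  d2 <- outer(fg[, 1], bg[, 1], "-")^2 + outer(fg[, 2], bg[, 2], "-")^2
  d <- matrix(0, nr + 2L, nc + 2L)
  d[pm] <- sqrt(apply(d2, 1, min))
  d[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

# Brute-force periphery/intermediate/core labels from brute_depth.
brute_regions <- function(mask) {
  depth <- brute_depth(mask)
  R <- max(depth)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[depth > 0] <- 1L
  labels[depth > R / 3] <- 2L
  labels[depth > 2 * R / 3] <- 3L
  labels
}

# Connected random blob: a chain of overlapping discs inside an n x n frame.
random_blob <- function(n, seed) {
  set.seed(seed)
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  k <- sample(2:4, 1)
  centre <- runif(2, n * 0.3, n * 0.7)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(k)) {
    r <- runif(1, n / 10, n / 4)
    mask <- mask | (sqrt((rr - centre[1])^2 + (cc - centre[2])^2) <= r)
    # next disc centred inside the current one so the blob stays connected
    theta <- runif(1, 0, 2 * pi)
    step <- runif(1, 0, r)
    centre <- pmin(pmax(centre + step * c(cos(theta), sin(theta)), 1), n)
  }
  mask
}

# Hard-edged disc mask in an n x n frame.
disc_mask <- function(n, radius, centre = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  sqrt((rr - centre[1])^2 + (cc - centre[2])^2) <= radius
}
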