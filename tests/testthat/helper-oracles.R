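# Independent brute-force oracles, deliberately written without reusing any
# of the package's optimised code paths.

reflect101_r <- function(i, n) {
  # 0-based index reflected into [0, n)
  if (n == 1) return(0L)
  period <- 2L * (n - 1L)
  i <- i %% period
  ifelse(i < n, i, period - i)
}

# naive full 2-D convolution with reflect-101 borders
conv2_naive <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  r <- (nrow(kernel) - 1L) / 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- reflect101_r(i - 1L + di, nr) + 1L
          jj <- reflect101_r(j - 1L + dj, nc) + 1L
          acc <- acc + kernel[di + r + 1L, dj + r + 1L] * img[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# naive variance-of-Laplacian: double-loop 4-neighbour Laplacian, population
# variance
lv_naive <- function(img) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- conv2_naive(img, k)
  mean((resp - mean(resp))^2)
}

# exhaustive pairwise AUC with ties counting 1/2
auc_pairwise <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# linear-interpolation percentile between closest order statistics
percentile_naive <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# brute-force routing: walk the thresholds one by one
route_naive <- function(theta, tau) {
  m <- length(tau) + 1L
  vapply(theta, function(th) {
    if (m == 1L) return(1L)
    if (th > tau[1L]) return(1L)
    for (k in seq_len(m - 2L)) {
      if (th > tau[k + 1L] && th <= tau[k]) return(k + 1L)
    }
    m
  }, integer(1))
}

# reference (pure-R) implementation of the tile descriptor
extract_features_ref <- function(tile, blob_depths = c(45, 25)) {
  lum <- to_luminance(tile)
  sm1 <- apply_blur(lum, 1); sm2 <- apply_blur(lum, 2); sm4 <- apply_blur(lum, 4)
  grad_energy <- function(m) {
    n <- nrow(m); p <- ncol(m)
    dx <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / 2
    dy <- (m[, 3:p, drop = FALSE] - m[, 1:(p - 2), drop = FALSE]) / 2
    mean(dx^2) + mean(dy^2)
  }
  blob_count <- function(m, depth) {
    thr <- median(m) - depth
    cnt <- 0L
    for (i in 2:(nrow(m) - 1L)) {
      for (j in 2:(ncol(m) - 1L)) {
        v <- m[i, j]
        if (v < thr && all(v < m[(i - 1):(i + 1), (j - 1):(j + 1)][-5]))
          cnt <- cnt + 1L
      }
    }
    cnt
  }
  h <- tabulate(pmin(pmax(floor(lum / 8) + 1, 1), 32), 32)
  ph <- h[h > 0] / sum(h)
  raw <- c(mean = mean(lum), sd = sd(as.vector(lum)),
           lv_s0 = lv_naive(lum), lv_s1 = lv_naive(sm1),
           lv_s2 = lv_naive(sm2), lv_s4 = lv_naive(sm4),
           grad_s1 = grad_energy(sm1), grad_s2 = grad_energy(sm2),
           blob_s1 = blob_count(sm1, blob_depths[1]),
           blob_s2 = blob_count(sm2, blob_depths[2]),
           coarse_energy = sd(as.vector(sm4)),
           entropy = -sum(ph * log2(ph)))
  en <- c("sd", "lv_s0", "lv_s1", "lv_s2", "lv_s4", "grad_s1", "grad_s2",
          "blob_s1", "blob_s2", "coarse_energy")
  raw[en] <- log1p(raw[en])
  raw
}

# small textured test tile drawn from the current RNG stream
random_tile <- function(n = 16, lo = 0, hi = 255) {
  matrix(runif(n * n, lo, hi), n, n)
}

# compact synthetic cohort for functional tests
tiny_cohort <- function(n_patients = 10, tiles = 4, size = 64, seed = 42, ...) {
  generate_cohort(synthetic_config(n_patients = n_patients,
                                   tiles_per_slide = tiles, tile_size = size,
                                   seed = seed, ...))
}
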