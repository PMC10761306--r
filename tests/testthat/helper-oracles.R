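# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each definition, and never call the
# package's optimized code paths.

# O(|A||B|) double-loop modified Hausdorff distance
mhd_bruteforce <- function(A, B) {
  dAB <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
    dAB <- dAB + best
  }
  dAB <- dAB / nrow(A)
  dBA <- 0
  for (j in seq_len(nrow(B))) {
    best <- Inf
    for (i in seq_len(nrow(A))) {
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
    dBA <- dBA + best
  }
  dBA <- dBA / nrow(B)
  max(dAB, dBA)
}

# BFS flood-fill component labeling oracle
label_floodfill <- function(mask, connectivity = 8L) {
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  nxt <- 0L
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (!mask[i, j] || lab[i, j] > 0L) next
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          q <- p + nb[k, ]
          if (q[1] < 1 || q[1] > H || q[2] < 1 || q[2] > W) next
          if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nxt
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu: maximize between-class variance over candidate thresholds
# k/n_bins * max, classifying by value >= threshold.
otsu_exhaustive <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  m <- max(v)
  best_t <- 0
  best_s <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    thr <- k / n_bins * m
    fg <- v >= thr
    w1 <- mean(fg)
    w0 <- 1 - w1
    if (w0 == 0 || w1 == 0) next
    s <- w0 * w1 * (mean(v[fg]) - mean(v[!fg]))^2
    if (s > best_s) {
      best_s <- s
      best_t <- thr
    }
  }
  best_t
}

# random point set in a box, 0-based coordinates
random_point_set <- function(n, lim = 40) {
  cbind(runif(n, 0, lim), runif(n, 0, lim))
}

# small in-memory dataset for network tests
tiny_sim_dataset <- function(n = 12L, size = 32L, seed = 5L) {
  cfg <- sim_config(image_size = c(size, size), seed = seed,
                    length_frac_range = c(0.4, 0.7), margin = 4L)
  simulate_dataset(cfg, n, split = c(0.6, 0.2, 0.2))
}
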