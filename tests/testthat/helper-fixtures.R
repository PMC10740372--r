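# Shared fixtures: tiny phantoms and cohorts built in code at test time.

tiny_spec <- function(shape = c(32, 32, 32)) {
  phantom_spec(volume_shape = shape, gland_axes = c(7, 9),
               lesion_radius_range = c(2.5, 3.5), heart_radius_range = c(4, 5))
}

random_volume <- function(shape = c(6, 6, 6), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  image_volume(array(rnorm(prod(shape)), shape), spacing = spacing)
}

random_mask <- function(shape = c(6, 6, 6), p = 0.3, spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  label_mask(array(as.integer(runif(prod(shape)) < p), shape), spacing = spacing)
}

# brute-force loss oracles: explicit nested loops over voxels and classes
ce_oracle <- function(u, v, eps = 1e-7) {
  N <- nrow(u); K <- ncol(u)
  acc <- 0
  for (i in seq_len(N)) for (k in seq_len(K)) {
    acc <- acc - v[i, k] * log(max(u[i, k], eps))
  }
  acc / N
}

dice_oracle <- function(u, v, eps = 1e-5) {
  K <- ncol(u)
  acc <- 0
  for (k in seq_len(K)) {
    num <- eps; den <- eps
    for (i in seq_len(nrow(u))) {
      num <- num + u[i, k] * v[i, k]
      den <- den + u[i, k] + v[i, k]
    }
    acc <- acc + num / den
  }
  -(2 / K) * acc
}

random_prob_pair <- function(N, K, seed) {
  set.seed(seed)
  u <- matrix(stats::rexp(N * K), N, K)
  u <- u / rowSums(u)
  v <- one_hot(sample(0:(K - 1), N, replace = TRUE), K)
  list(u = u, v = v)
}

# brute-force overlap/surface oracles on voxel index sets
dice_oracle_masks <- function(a, b) {
  A <- which(a$data > 0); B <- which(b$data > 0)
  if (length(A) == 0 && length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

iou_oracle_masks <- function(a, b) {
  A <- which(a$data > 0); B <- which(b$data > 0)
  if (length(A) == 0 && length(B) == 0) return(1)
  length(intersect(A, B)) / length(union(A, B))
}

hd95_oracle <- function(a, b, percentile = 95) {
  surf <- function(m) {
    d <- dim(m$data)
    keep <- matrix(0, 0, 3)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m$data[i, j, k] > 0) {
        on_surface <- FALSE
        for (off in list(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0), c(0,0,-1), c(0,0,1))) {
          ni <- i + off[1]; nj <- j + off[2]; nk <- k + off[3]
          if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3] ||
              m$data[ni, nj, nk] == 0) { on_surface <- TRUE; break }
        }
        if (on_surface) keep <- rbind(keep, (c(i, j, k) - 1) * m$spacing)
      }
    }
    keep
  }
  sa <- surf(a); sb <- surf(b)
  dists <- c()
  for (i in seq_len(nrow(sa))) {
    dists <- c(dists, sqrt(min(colSums((t(sb) - sa[i, ])^2))))
  }
  for (i in seq_len(nrow(sb))) {
    dists <- c(dists, sqrt(min(colSums((t(sa) - sb[i, ])^2))))
  }
  as.numeric(stats::quantile(dists, percentile / 100, type = 7))
}

# empirical two-sample Kolmogorov-Smirnov distance
ks_distance <- function(x, y) {
  as.numeric(suppressWarnings(stats::ks.test(x, y)$statistic))
}
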