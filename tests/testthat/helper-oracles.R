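# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive quantities with plain loops, not by calling
# the implementation under test.

# Exhaustive BMU scan with lexicographic (j, k) tie-break.
oracle_bmu <- function(W, J, K, x) {
  best <- Inf; bj <- NA; bk <- NA
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      u <- (j - 1) * K + k
      d <- sum((x - W[u, ])^2)
      if (d < best) { best <- d; bj <- j; bk <- k }
    }
  }
  c(bj, bk)
}

# Per-unit U value recomputed from the component definitions with loops.
oracle_umatrix <- function(W, J, K) {
  wv <- function(j, k) W[(j - 1) * K + k, ]
  U <- matrix(0, J, K)
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      comps <- numeric(0)
      for (dj in c(-1, 1)) {
        if (j + dj >= 1 && j + dj <= J) {
          comps <- c(comps, sum((wv(j, k) - wv(j + dj, k))^2))
        }
      }
      for (dk in c(-1, 1)) {
        if (k + dk >= 1 && k + dk <= K) {
          comps <- c(comps, sum((wv(j, k) - wv(j, k + dk))^2))
        }
      }
      for (dj in c(-1, 1)) {
        for (dk in c(-1, 1)) {
          if (j + dj >= 1 && j + dj <= J && k + dk >= 1 && k + dk <= K) {
            comps <- c(comps,
                       0.5 * sum((wv(j, k) - wv(j + dj, k + dk))^2) +
                       0.5 * sum((wv(j + dj, k) - wv(j, k + dk))^2))
          }
        }
      }
      U[j, k] <- if (length(comps)) mean(comps) else 0
    }
  }
  U
}

# Mean Euclidean quantization error by direct scan.
oracle_mean_deviation <- function(W, data) {
  tot <- 0
  for (r in seq_len(nrow(data))) {
    best <- Inf
    for (u in seq_len(nrow(W))) {
      d <- sqrt(sum((data[r, ] - W[u, ])^2))
      if (d < best) best <- d
    }
    tot <- tot + best
  }
  tot / nrow(data)
}

random_grid <- function(J, K, I, seed) {
  set.seed(seed)
  moodmap:::new_som_grid(matrix(rnorm(J * K * I), J * K, I), J, K)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Well-separated prototype set: `sizes[i]` vectors around center i.
planted_prototypes <- function(sizes, dim = 6, sep = 8, noise = 0.2,
                               seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(length(sizes) * dim), length(sizes), dim)
  centers <- centers / sqrt(rowSums(centers^2)) * sep *
    seq_along(sizes)
  do.call(rbind, lapply(seq_along(sizes), function(g) {
    matrix(rnorm(sizes[g] * dim, 0, noise), sizes[g], dim) +
      rep(centers[g, ], each = sizes[g])
  }))
}
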