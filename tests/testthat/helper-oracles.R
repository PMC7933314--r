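# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain-loop enumeration and textbook formulas.

# Exhaustive voxel scan for the isocontour volume: count voxels inside the
# VOI at or above pct% of the VOI-local maximum, one voxel at a time.
brute_force_isocontour <- function(values, voi, pct, spacing_mm) {
  vmax <- -Inf
  d <- dim(values)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (voi[i, j, k] && values[i, j, k] > vmax) vmax <- values[i, j, k]
  }
  thr <- pct / 100 * vmax
  count <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (voi[i, j, k] && values[i, j, k] >= thr) count <- count + 1L
  }
  list(count = count, ml = count * prod(spacing_mm) / 1000)
}

# Textbook concordance coefficient from explicit sums (1/n moments).
textbook_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# R-squared by solving the normal equations directly.
normal_equations_r2 <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

# Pooled two-sample t statistic from first principles.
textbook_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# A small random blurred-blob map for volumetry property tests.
random_test_map <- function(seed, dim = c(14, 12, 10), spacing = c(2, 2, 3)) {
  set.seed(seed)
  vals <- array(stats::rexp(prod(dim)), dim)
  # smooth crudely so maps are not pure white noise
  for (rep in 1:2) {
    vals <- (vals +
             vals[c(1, seq_len(dim[1] - 1)), , ] +
             vals[c(seq_len(dim[1] - 1) + 1, dim[1]), , ]) / 3
  }
  activity_map(vals, spacing)
}
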