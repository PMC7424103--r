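# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Direct 2-D cross-correlation (valid region), plain loops.
direct_xcorr <- function(image, kernel) {
  k <- nrow(kernel)
  n <- nrow(image) - k + 1
  m <- ncol(image) - k + 1
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    out[i, j] <- sum(image[i:(i + k - 1), j:(j + k - 1)] * kernel)
  }
  out
}

# Excess-free kurtosis of the valid-region outputs of a fixed 3x3 oriented
# filter; used as the fourth-moment statistic for planted-structure checks.
filter_kurtosis_oracle <- function(image) {
  f <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  v <- as.vector(direct_xcorr(image, f))
  m <- mean(v)
  mean((v - m)^4) / mean((v - m)^2)^2
}

# Exhaustive best equally weighted k-subset (for small n).
exhaustive_subset_error <- function(M, target, k) {
  combs <- utils::combn(nrow(M), k)
  errs <- apply(combs, 2, function(idx)
    sqrt(sum((colMeans(M[idx, , drop = FALSE]) - target)^2)))
  min(errs)
}

# Simplex grid search with box refinement: enumeration-only oracle for the
# constrained quadratic min ||M'w - t||^2 + lambda ||w||^2, n in {2, 3, 4}.
simplex_grid_objective <- function(M, target, lambda = 0) {
  n <- nrow(M)
  stopifnot(n >= 2, n <= 4)
  obj <- function(W) {
    fit <- W %*% M            # rows: candidate w
    colSums((t(fit) - target)^2) + lambda * rowSums(W^2)
  }
  grid_pts <- function(lo, hi, h) {
    vals <- lapply(seq_len(n - 1), function(i) seq(max(0, lo[i]),
                                                   min(1, hi[i]), by = h))
    W <- as.matrix(expand.grid(vals))
    last <- 1 - rowSums(W)
    keep <- last >= max(0, lo[n]) - 1e-12 & last <= min(1, hi[n]) + 1e-12
    cbind(W[keep, , drop = FALSE], last[keep])
  }
  best <- rep(1 / n, n)
  steps <- c(0.02, 0.002, 2e-4)
  radii <- c(1, 0.03, 0.003)
  for (lvl in seq_along(steps)) {
    W <- grid_pts(best - radii[lvl], best + radii[lvl], steps[lvl])
    vals <- obj(W)
    best <- W[which.min(vals), ]
  }
  list(objective = min(obj(matrix(best, 1))), w = best)
}

# M has one row per neuron; w lives on the simplex.
objective_value <- function(M, target, w, lambda = 0) {
  sum((drop(crossprod(M, w)) - target)^2) + lambda * sum(w^2)
}

# Small random modulation profile (all entries defined).
random_profile <- function(n, f, seed) {
  set.seed(seed)
  modulation_profile(matrix(stats::runif(n * f, -0.9, 0.9), n, f))
}
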