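# Independent oracles used to cross-check the implementation. These are
# written from the textbook definitions and share no code with the package.

# Cox-de Boor recursion for a single B-spline basis function B_{i,k}(x) on
# the full (augmented) knot sequence t, degree k, zero-based index i.
cox_de_boor <- function(i, k, x, t) {
  if (k == 0) {
    # half-open spans, except the last non-empty span which is closed so
    # the right endpoint is covered
    last <- max(which(t < t[length(t)]))
    if (i + 1 == last) return(as.numeric(x >= t[i + 1] & x <= t[i + 2]))
    return(as.numeric(x >= t[i + 1] & x < t[i + 2]))
  }
  left <- 0
  d1 <- t[i + k + 1] - t[i + 1]
  if (d1 > 0) left <- (x - t[i + 1]) / d1 * cox_de_boor(i, k - 1, x, t)
  right <- 0
  d2 <- t[i + k + 2] - t[i + 2]
  if (d2 > 0) right <- (t[i + k + 2] - x) / d2 * cox_de_boor(i + 1, k - 1, x, t)
  left + right
}

# Full basis matrix from the recursion oracle.
oracle_basis <- function(x, breakpoints, degree) {
  t <- c(rep(breakpoints[1], degree), breakpoints,
         rep(breakpoints[length(breakpoints)], degree))
  p <- length(breakpoints) - 2 + degree + 1
  sapply(seq_len(p) - 1, function(i)
    vapply(x, function(xx) cox_de_boor(i, degree, xx, t), numeric(1)))
}

# Normal-equations least-squares solution assembled from the basis oracle.
oracle_lsq_coef <- function(x, y, breakpoints, degree) {
  B <- oracle_basis(x, breakpoints, degree)
  solve(crossprod(B), crossprod(B, y))
}

# Exhaustive single-removal step: the interior-knot index whose removal
# minimizes the refit SSE (leftmost on ties), plus that SSE.
oracle_best_removal <- function(x, y, breakpoints, degree) {
  interior <- seq(2, length(breakpoints) - 1)
  sses <- vapply(interior, function(i) {
    B <- oracle_basis(x, breakpoints[-i], degree)
    co <- solve(crossprod(B), crossprod(B, y))
    sum((y - B %*% co)^2)
  }, numeric(1))
  list(drop = interior[which.min(sses)], sse = min(sses))
}

# Small deterministic synthetic sweep set shared by several tests.
make_test_sweeps <- function(levels = c(0.03125, 0.125, 0.5), noise_sd = 0,
                             seed = 42L, replicates = 1L) {
  generate_dataset(levels_eth = levels, levels_ace = levels,
                   replicates = replicates, params = calibrate_amplitudes(),
                   noise_sd = noise_sd, seed = seed)
}
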