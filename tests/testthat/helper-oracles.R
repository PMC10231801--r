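# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exact two-sided signed-rank p-value by brute-force enumeration of all 2^n
# sign assignments (tie-free inputs)
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(sign(d) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  w_all <- signs %*% r
  mean(abs(w_all) >= abs(w_obs) - 1e-9)
}

# direct cumulative-min BH formula, independent of bh_adjust's implementation
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- numeric(m)
  for (k in seq_len(m)) adj[k] <- min(1, min(ranked[k:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# textbook BH step-up rejection set at level q
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- max(c(0, which(p[o] <= q * seq_len(m) / m)))
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# PVE via per-variable regression R^2: average squared multiple correlation
# of each variable on the subset, computed by explicit least squares on a
# large sample drawn from N(0, R)
pve_regression_oracle <- function(R, subset_idx, n = 20000, seed = 99) {
  withr::with_seed(seed, {
    L <- chol(R)
    X <- matrix(stats::rnorm(n * nrow(R)), n) %*% L
    r2 <- vapply(seq_len(ncol(X)), function(j) {
      fit <- stats::lm.fit(cbind(1, X[, subset_idx, drop = FALSE]), X[, j])
      1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    }, numeric(1))
    100 * mean(r2)
  })
}

# closed-form PVE from the matrix identity (kept separate from pve() so the
# two routes stay independent): average squared multiple correlation
pve_formula_oracle <- function(R, subset_idx) {
  Rss <- R[subset_idx, subset_idx, drop = FALSE]
  Rxs <- R[, subset_idx, drop = FALSE]
  smc <- diag(Rxs %*% solve(Rss) %*% t(Rxs)) / diag(R)
  100 * mean(smc)
}

random_correlation <- function(p, seed) {
  withr::with_seed(seed, {
    A <- matrix(stats::rnorm(p * p), p)
    stats::cov2cor(crossprod(A) + diag(p) * 0.5)
  })
}
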