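# Independent brute-force oracles used across the test files.  These
# deliberately re-derive each quantity from its definition through a
# different code path than the package implementation.

# distance correlation via explicit double-centering of full matrices
dcor_oracle <- function(a, b) {
  ctr <- function(M) sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + mean(M)
  A <- ctr(abs(outer(a, a, "-")))
  B <- ctr(abs(outer(b, b, "-")))
  daa <- mean(A * A)
  dbb <- mean(B * B)
  if (daa <= 0 || dbb <= 0) return(0)
  sqrt(max(mean(A * B), 0)) / (daa * dbb)^0.25
}

# smallest k such that the top-k prefix of the order contains all causal
# features (prefix scan)
mms_oracle <- function(ord, causal) {
  for (k in seq_along(ord)) {
    if (all(causal %in% ord[seq_len(k)])) return(k)
  }
  stop("causal features not contained in the ranking")
}

# exhaustive best single-feature regression split: midpoint threshold
# minimising the summed child SSE over the n-1 candidate cuts
best_split_oracle <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  best <- Inf; thr <- NA_real_
  for (k in seq_len(n - 1)) {
    if (x[k + 1] <= x[k]) next
    yl <- y[seq_len(k)]; yr <- y[(k + 1):n]
    sse <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
    if (sse < best - 1e-12) {
      best <- sse
      thr <- (x[k] + x[k + 1]) / 2
    }
  }
  thr
}

# marginal |Pearson correlation| ranking (the SIS equivalence oracle)
pearson_rank_oracle <- function(X, y) {
  sc <- abs(apply(X, 2, function(col) stats::cor(col, y)))
  order(-sc, seq_len(ncol(X)))
}

expect_permutation <- function(ord, p) {
  expect_setequal(ord, seq_len(p))
  expect_length(ord, p)
}
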