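# From-definition oracles, kept independent of the package implementations.

# Holm step-down: sort ascending, multiply by (m - i + 1), running max, cap.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- pmin(cummax((m - seq_len(m) + 1) * p[ord]), 1)
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# BH step-up: sort descending, multiply by m / rank, running min, cap.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ranks <- m - seq_len(m) + 1  # rank of each sorted-descending element
  adj_sorted <- pmin(cummin(m / ranks * p[ord]), 1)
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Exact hypergeometric upper tail by combinatorial enumeration.
hyper_enum_oracle <- function(N, C, n, O) {
  ks <- O:min(C, n)
  sum(choose(C, ks) * choose(N - C, n - ks)) / choose(N, n)
}

# Propagation by truncated Neumann series sum_k (alpha S)^k y -- an
# independent route to the same fixed point as the linear solve.
propagate_series_oracle <- function(A, query_idx, alpha, iter = 2000) {
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- A * (inv_sqrt %o% inv_sqrt)
  y <- numeric(nrow(A))
  y[query_idx] <- 1 / length(query_idx)
  s <- y
  term <- y
  for (k in seq_len(iter)) {
    term <- alpha * (S %*% term)
    s <- s + term
    if (max(abs(term)) < 1e-14) break
  }
  as.numeric(s)
}
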