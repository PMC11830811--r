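# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Partial correlation via residual regression: correlate the residuals of
# x_i ~ all-others and x_j ~ all-others.
oracle_partial_correlation <- function(ts) {
  k <- ncol(ts)
  r <- diag(0, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      others <- ts[, -c(i, j), drop = FALSE]
      ri <- if (ncol(others)) resid(lm.fit(cbind(1, others), ts[, i])) else ts[, i] - mean(ts[, i])
      rj <- if (ncol(others)) resid(lm.fit(cbind(1, others), ts[, j])) else ts[, j] - mean(ts[, j])
      r[i, j] <- r[j, i] <- cor(ri, rj)
    }
  }
  dimnames(r) <- list(colnames(ts), colnames(ts))
  r
}

# Hypergeometric upper tail by exhaustive subset enumeration: place the m
# significant items on all subsets of N positions (first n_in are "in") and
# count subsets with at least k_in inside.
oracle_enrichment_enum <- function(k_in, n_in, k_out, n_out) {
  m <- k_in + k_out
  n_total <- n_in + n_out
  if (m == 0) return(1)
  subsets <- utils::combn(n_total, m)
  hits <- colSums(subsets <= n_in)
  mean(hits >= k_in)
}

# Least-squares recovery of mixing coefficients from maps (pseudoinverse,
# built independently of extract_timeseries).
oracle_spatial_coefs <- function(x, y) {
  solve(t(x) %*% x, t(x) %*% y)
}

# Small helper: random positive-definite precision via random partial
# correlations on a chain graph.
chain_gt <- function(r12, r23, nodes = c("A", "B", "C")) {
  make_ground_truth(
    data.frame(region_i = nodes[c(1, 2)], region_j = nodes[c(2, 3)],
               r = c(r12, r23)),
    nodes = nodes
  )
}
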