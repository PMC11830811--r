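# Internal helpers shared across modules.

# Deterministic substream seed derived from a root seed and a label, kept
# below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, label, k = 0L) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + k * 104729) %% 2147483629)
}

# Run `expr` under a local RNG state seeded with `seed`; if seed is NULL the
# global RNG stream is consumed as-is.
with_seed_or_global <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Canonical unordered connection key "a--b" with the two labels in the order
# they appear in `nodes` (so keys are stable across input orderings).
connection_key <- function(region_i, region_j, nodes) {
  ii <- match(region_i, nodes)
  jj <- match(region_j, nodes)
  a <- ifelse(ii <= jj, region_i, region_j)
  b <- ifelse(ii <= jj, region_j, region_i)
  paste0(a, "--", b)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "coinet_bad_argument")
  }
  invisible(x)
}

check_edge_frame <- function(edges, nodes, value_col, range_open_unit = FALSE) {
  if (!is.data.frame(edges)) {
    abort("`edges` must be a data frame with columns region_i, region_j.",
          class = "coinet_bad_argument")
  }
  need <- c("region_i", "region_j", value_col)
  miss <- setdiff(need, names(edges))
  if (length(miss)) {
    abort(paste0("`edges` is missing column(s): ", paste(miss, collapse = ", ")),
          class = "coinet_bad_argument")
  }
  unknown <- setdiff(c(edges$region_i, edges$region_j), nodes)
  if (length(unknown)) {
    abort(paste0("Unknown region label(s): ", paste(unique(unknown), collapse = ", ")),
          class = "coinet_unknown_node")
  }
  if (any(edges$region_i == edges$region_j)) {
    abort("Self-connections are not allowed.", class = "coinet_bad_argument")
  }
  v <- edges[[value_col]]
  if (!all(is.finite(v))) {
    abort(sprintf("Column `%s` must be finite.", value_col),
          class = "coinet_bad_argument")
  }
  if (range_open_unit && any(abs(v) >= 1)) {
    abort(sprintf("Column `%s` must lie strictly inside (-1, 1).", value_col),
          class = "coinet_bad_partial_correlation")
  }
  invisible(edges)
}
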