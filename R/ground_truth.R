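# Ground-truth Gaussian graphical models for the synthetic-data generator.

# Partial correlations implied by a precision matrix:
# r_ij = -P_ij / sqrt(P_ii P_jj), diagonal set to 1.
partial_from_precision <- function(P) {
  d <- sqrt(diag(P))
  r <- -P / tcrossprod(d)
  diag(r) <- 1
  r
}

# Repair a symmetric matrix to positive definiteness by adding the smallest
# multiple of the identity that lifts the minimum eigenvalue to `floor`.
pd_repair <- function(P, floor = 1e-6) {
  P <- (P + t(P)) / 2
  ev_min <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < floor) {
    P <- P + diag(floor - ev_min, nrow(P))
  }
  P
}

#' Build a ground-truth partial-correlation network
#'
#' Constructs a Gaussian graphical model over the given nodes whose
#' precision matrix implies the requested partial correlations. The
#' precision matrix starts from the identity, each listed edge (i, j) sets
#' `P[i, j] = -r_ij`, and the result is repaired to positive definiteness
#' by adding the smallest multiple of the identity lifting the minimum
#' eigenvalue to `1e-6`. The repair shrinks implied partial correlations
#' slightly when the requested graph is not already positive definite; the
#' realized values are stored in `partial`.
#'
#' @param edges Data frame with columns `region_i`, `region_j`, `r`
#'   (requested partial correlation, strictly inside (-1, 1)). May have
#'   zero rows for an independence network.
#' @param nodes Character vector of distinct region labels
#'   (default [clipst_nodes()]).
#' @param jitter Standard deviation of zero-mean Gaussian noise added to
#'   each requested `r` (on the correlation scale) before construction;
#'   used for per-subject heterogeneity. Default 0.
#' @param seed Integer seed for the jitter draw (ignored when `jitter = 0`).
#' @return An object of class `gt_network`: list with `nodes`, `precision`
#'   (K x K positive definite), `partial` (implied partial correlations,
#'   diagonal 1), and `edges` (the request, with realized values attached).
#' @export
#' @examples
#' gt <- make_ground_truth(data.frame(region_i = "dmPFC", region_j = "dlPFC",
#'                                    r = 0.5))
#' gt$partial["dmPFC", "dlPFC"]
make_ground_truth <- function(edges = NULL, nodes = clipst_nodes(),
                              jitter = 0, seed = NULL) {
  if (anyDuplicated(nodes)) {
    abort("Region labels must be distinct.", class = "coinet_bad_argument")
  }
  k <- length(nodes)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble(region_i = character(), region_j = character(), r = numeric())
  }
  edges <- as_tibble(edges)
  check_edge_frame(edges, nodes, "r", range_open_unit = TRUE)
  key <- if (nrow(edges)) connection_key(edges$region_i, edges$region_j, nodes) else character()
  if (anyDuplicated(key)) {
    abort("Duplicate edges in `edges`.", class = "coinet_bad_argument")
  }

  r_req <- edges$r
  if (jitter > 0 && nrow(edges)) {
    r_req <- with_seed_or_global(seed, r_req + rnorm(nrow(edges), 0, jitter))
    r_req <- pmin(pmax(r_req, -0.99), 0.99)
  }

  P <- diag(k)
  dimnames(P) <- list(nodes, nodes)
  for (row in seq_len(nrow(edges))) {
    i <- match(edges$region_i[row], nodes)
    j <- match(edges$region_j[row], nodes)
    P[i, j] <- P[j, i] <- -r_req[row]
  }
  P <- pd_repair(P)
  partial <- partial_from_precision(P)
  if (nrow(edges)) {
    edges$r_requested <- r_req
    edges$r_realized <- partial[cbind(match(edges$region_i, nodes),
                                      match(edges$region_j, nodes))]
  }
  structure(list(nodes = nodes, precision = P, partial = partial, edges = edges),
            class = "gt_network")
}

#' Default CLIPST ground-truth network
#'
#' The 39 connections of interest of the shipped CLIPST grid, each at a
#' common baseline partial correlation.
#'
#' @param r Baseline partial correlation on every COI edge (default 0.2).
#' @return A `gt_network` object.
#' @export
default_ground_truth <- function(r = 0.2) {
  e <- clipst_coi_edges()
  e$r <- r
  make_ground_truth(e[, c("region_i", "region_j", "r")], clipst_nodes())
}

#' @export
print.gt_network <- function(x, ...) {
  off <- x$partial[upper.tri(x$partial)]
  cat(sprintf("<gt_network> %d nodes, %d nonzero edges, max |partial r| = %.3f\n",
              length(x$nodes), sum(abs(off) > 1e-12), max(abs(off))))
  invisible(x)
}

#' @export
as_tibble.gt_network <- function(x, ...) {
  conns <- all_connections(x$nodes)
  conns$r_partial <- x$partial[cbind(match(conns$region_i, x$nodes),
                                     match(conns$region_j, x$nodes))]
  conns
}

# Apply a treatment effect on the Fisher-z partial-correlation scale:
# z' = atanh(r) + delta_z on each listed edge, then rebuild the precision
# entry and re-repair to PD. Returns a new gt_network.
apply_effect <- function(gt, effect_edges) {
  if (is.null(effect_edges) || nrow(effect_edges) == 0L) return(gt)
  check_edge_frame(effect_edges, gt$nodes, "delta_z")
  P <- gt$precision
  partial <- gt$partial
  for (row in seq_len(nrow(effect_edges))) {
    i <- match(effect_edges$region_i[row], gt$nodes)
    j <- match(effect_edges$region_j[row], gt$nodes)
    r_old <- partial[i, j]
    if (abs(r_old) >= 1) {
      abort("Existing partial correlation has magnitude >= 1.",
            class = "coinet_bad_partial_correlation")
    }
    r_new <- tanh(atanh(r_old) + effect_edges$delta_z[row])
    if (!is.finite(r_new) || abs(r_new) >= 1) {
      abort("Effect pushes a partial correlation to magnitude >= 1.",
            class = "coinet_bad_partial_correlation")
    }
    P[i, j] <- P[j, i] <- -r_new * sqrt(P[i, i] * P[j, j])
  }
  P <- pd_repair(P)
  structure(list(nodes = gt$nodes, precision = P,
                 partial = partial_from_precision(P), edges = gt$edges),
            class = "gt_network")
}
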