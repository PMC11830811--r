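#' Exact enrichment tail probability for a connection-of-interest split
#'
#' One-sided exact test (Fisher/hypergeometric) that significant connections
#' concentrate inside the connection-of-interest (COI) set. With
#' `m = k_in + k_out` significant connections among `N = n_in + n_out`
#' total, the p-value is `P[X >= k_in]` for `X ~ hypergeometric(N, n_in, m)`
#' — the probability, under random placement of the `m` significant
#' connections among all `N`, that at least `k_in` land inside the COI set.
#'
#' The tail is accumulated in log space from `lchoose()` terms, so it is
#' exact to double precision for any table size.
#'
#' @param k_in Number of significant COI connections.
#' @param n_in COI set size (39 in the shipped CLIPST grid).
#' @param k_out Number of significant non-COI connections.
#' @param n_out Non-COI set size (66 in the shipped grid).
#' @return The one-sided exact p-value, a number in (0, 1].
#' @export
#' @examples
#' fisher_exact_enrichment(4, 39, 0, 66)  # 0.0172 to 4 decimals
#' fisher_exact_enrichment(3, 39, 0, 66)  # 0.0488 to 4 decimals
fisher_exact_enrichment <- function(k_in, n_in, k_out, n_out) {
  for (nm in c("k_in", "n_in", "k_out", "n_out")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v < 0 || v != round(v)) {
      abort(sprintf("`%s` must be a nonnegative integer.", nm),
            class = "coinet_bad_counts")
    }
  }
  if (k_in > n_in || k_out > n_out) {
    abort("Significant counts cannot exceed their set sizes.",
          class = "coinet_bad_counts")
  }
  m <- k_in + k_out
  n_total <- n_in + n_out
  if (m == 0) return(1)
  x_hi <- min(n_in, m)
  xs <- seq.int(k_in, x_hi)
  xs <- xs[m - xs <= n_out]
  if (!length(xs)) return(0)
  log_terms <- lchoose(n_in, xs) + lchoose(n_out, m - xs) - lchoose(n_total, m)
  # log-sum-exp for a numerically clean tail
  mx <- max(log_terms)
  p <- exp(mx) * sum(exp(log_terms - mx))
  min(p, 1)
}

#' Count significant connections inside and outside a COI grid
#'
#' @param results Contrast results as returned by [run_contrasts()]: one row
#'   per connection with columns `region_i`, `region_j`, `phase`, `p`.
#' @param grid A [coi_grid()] object.
#' @param alpha Per-connection two-sided significance threshold, in (0, 1).
#' @param phase Which phase to classify: `"acute"` or `"delayed"`.
#' @return One-row tibble with columns `phase`, `k_in`, `n_in`, `k_out`,
#'   `n_out`, `alpha`.
#' @export
classify_connections <- function(results, grid, alpha = 0.05,
                                 phase = c("acute", "delayed")) {
  phase <- match.arg(phase)
  stopifnot(inherits(grid, "coi_grid"))
  stopifnot_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "coinet_bad_argument")
  }
  res <- dplyr::filter(as_tibble(results), .data$phase == !!phase)
  if (!nrow(res)) {
    abort(paste0("No results for phase '", phase, "'."),
          class = "coinet_missing_connections")
  }
  res$connection <- connection_key(res$region_i, res$region_j, grid$nodes)
  if (anyDuplicated(res$connection)) {
    abort("Multiple results for the same connection within one phase.",
          class = "coinet_bad_argument")
  }
  missing <- setdiff(grid$all$connection, res$connection)
  if (length(missing)) {
    abort(paste0("Results missing for ", length(missing), " connection(s), e.g. ",
                 paste(head(missing, 3), collapse = ", ")),
          class = "coinet_missing_connections")
  }
  res <- dplyr::left_join(res, grid$all[, c("connection", "is_coi")],
                          by = "connection")
  tibble(
    phase = phase,
    k_in = sum(res$p < alpha & res$is_coi),
    n_in = sum(grid$all$is_coi),
    k_out = sum(res$p < alpha & !res$is_coi),
    n_out = sum(!grid$all$is_coi),
    alpha = alpha
  )
}

#' Enrichment test of significant connections in the COI set
#'
#' For each phase present in `results`, counts significant connections
#' inside/outside the COI grid at threshold `alpha` and computes the
#' one-sided exact tail probability with [fisher_exact_enrichment()].
#'
#' @inheritParams classify_connections
#' @param phases Phases to test; defaults to those present in `results`.
#' @return An object of class `coi_enrichment`; use [tidy()] for the
#'   per-phase table and [glance()] for a one-row summary.
#' @export
#' @examples
#' g <- clipst_coi_grid()
#' res <- all_connections()
#' res$phase <- "acute"
#' res$p <- ifelse(res$connection %in% c("vmPFC--NAcc", "omPFC--Thalamus",
#'                                       "vlPFC--Thalamus", "dlPFC--omPFC"),
#'                 0.01, 0.5)
#' enrichment_test(res, g, alpha = 0.05)
enrichment_test <- function(results, grid = clipst_coi_grid(), alpha = 0.05,
                            phases = NULL) {
  results <- as_tibble(results)
  if (is.null(phases)) phases <- unique(results$phase)
  rows <- purrr::map_dfr(phases, function(ph) {
    counts <- classify_connections(results, grid, alpha = alpha, phase = ph)
    counts$p_exact <- fisher_exact_enrichment(counts$k_in, counts$n_in,
                                              counts$k_out, counts$n_out)
    counts
  })
  structure(list(table = rows, alpha = alpha, grid = grid),
            class = "coi_enrichment")
}

#' @export
print.coi_enrichment <- function(x, ...) {
  cat("Connection-of-interest enrichment (one-sided exact test)\n")
  cat(sprintf("  per-connection alpha = %g\n", x$alpha))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-8s %d/%d significant in COI vs %d/%d outside: p = %.4f\n",
                tb$phase[i], tb$k_in[i], tb$n_in[i], tb$k_out[i], tb$n_out[i],
                tb$p_exact[i]))
  }
  invisible(x)
}

#' @rdname enrichment_test
#' @param x A `coi_enrichment` object.
#' @param ... Unused.
#' @export
tidy.coi_enrichment <- function(x, ...) x$table

#' @rdname enrichment_test
#' @export
glance.coi_enrichment <- function(x, ...) {
  tb <- x$table
  out <- tibble(alpha = x$alpha, n_phases = nrow(tb))
  for (i in seq_len(nrow(tb))) {
    out[[paste0("p_", tb$phase[i])]] <- tb$p_exact[i]
  }
  out
}
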