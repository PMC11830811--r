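# Partial-correlation connectivity with Fisher r-to-z transformation.

#' Partial correlation matrix of a multivariate time series
#'
#' Inverts the sample correlation matrix (optionally ridge-regularized) and
#' normalizes: with `P = solve(cor(ts) + ridge * I)`, the partial
#' correlation between regions i and j given all others is
#' `r_ij = -P_ij / sqrt(P_ii * P_jj)`. Working from the correlation (not
#' covariance) matrix makes the measure invariant to per-region rescaling.
#' The diagonal of the returned matrix is 0 by convention (self-connections
#' never enter downstream counts).
#'
#' @param ts T x K numeric matrix, one column per region.
#' @param ridge Nonnegative L2 regularization weight added to the diagonal
#'   of the correlation matrix before inversion. Default 0 (exact); small
#'   values (e.g. 0.1) give FSLNets-style shrinkage for short series.
#' @return K x K symmetric matrix of partial correlations, diagonal 0.
#' @export
#' @examples
#' ts <- matrix(rnorm(600), 200, 3)
#' partial_correlation(ts)
partial_correlation <- function(ts, ridge = 0) {
  ts <- as.matrix(ts)
  t_len <- nrow(ts)
  k <- ncol(ts)
  stopifnot_scalar_number(ridge, "ridge")
  if (ridge < 0) {
    abort("`ridge` must be nonnegative.", class = "coinet_bad_argument")
  }
  if (ridge == 0 && t_len <= k + 2) {
    abort(sprintf("Need T > K + 2 (= %d) for an invertible correlation matrix at ridge = 0.",
                  k + 2), class = "coinet_bad_argument")
  }
  vars <- apply(ts, 2, stats::var)
  if (any(vars <= 0 | !is.finite(vars))) {
    bad <- colnames(ts)[vars <= 0 | !is.finite(vars)]
    abort(paste0("Zero-variance column(s): ",
                 paste(if (length(bad)) bad else which(vars <= 0), collapse = ", ")),
          class = "coinet_zero_variance")
  }
  s <- cor(ts)
  p <- tryCatch(
    solve(s + diag(ridge, k)),
    error = function(e) {
      abort("Correlation matrix is singular; increase `ridge` (e.g. 0.1).",
            class = "coinet_singular")
    }
  )
  d <- sqrt(diag(p))
  r <- -p / tcrossprod(d)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  dimnames(r) <- dimnames(s)
  r
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r)`, optionally scaled to an approximately standard-normal
#' statistic for partial correlations: with K regions, K-2 variables are
#' controlled for each pair, so the scaling factor is
#' `sqrt(T - (K - 2) - 3)`.
#'
#' @param r Numeric vector or matrix of (partial) correlations with
#'   `|r| < 1` off-diagonal; a matrix diagonal of 0 stays 0.
#' @param normalize Apply the standard-normal scaling (default FALSE).
#' @param t_len,k Number of time points and regions; required when
#'   `normalize = TRUE`.
#' @return Transformed values, same shape as `r`.
#' @export
#' @examples
#' fisher_z(0.5)                                   # atanh(0.5)
#' fisher_z(0.1, normalize = TRUE, t_len = 220, k = 15)
fisher_z <- function(r, normalize = FALSE, t_len = NULL, k = NULL) {
  vals <- if (is.matrix(r)) r[row(r) != col(r)] else r
  if (any(!is.finite(vals)) || any(abs(vals) >= 1)) {
    abort("All (off-diagonal) correlations must have |r| < 1.",
          class = "coinet_bad_partial_correlation")
  }
  z <- atanh(r)
  if (is.matrix(z)) diag(z) <- 0
  if (normalize) {
    if (is.null(t_len) || is.null(k)) {
      abort("`t_len` and `k` are required when normalize = TRUE.",
            class = "coinet_bad_argument")
    }
    dof <- t_len - (k - 2) - 3
    if (dof <= 0) {
      abort("T - (K - 2) - 3 must be positive for normalized z.",
            class = "coinet_bad_argument")
    }
    z <- z * sqrt(dof)
  }
  z
}

#' Per-scan connectivity table for a study
#'
#' Computes the partial-correlation matrix of every scan and returns the
#' upper triangle in long format, one row per scan x connection, with both
#' the raw partial correlation and its Fisher z score.
#'
#' @param study A `crossover_study` from [simulate_study()], or any list
#'   with elements `scans` (named list of T x K matrices) and `meta`
#'   (tibble with `scan_id`, `subject`, `period`, `treatment`,
#'   `timepoint`), e.g. from [read_timeseries_csv()].
#' @param ridge Passed to [partial_correlation()] (default 0).
#' @param normalize Use the standard-normal z scaling (default TRUE, so z
#'   magnitudes are comparable across scan lengths; the enrichment result
#'   is invariant to this monotone choice).
#' @return Tibble with columns `subject`, `period`, `treatment`,
#'   `timepoint`, `region_i`, `region_j`, `connection`, `r_partial`, `z`.
#' @export
connectivity <- function(study, ridge = 0, normalize = TRUE) {
  scans <- study$scans
  meta <- study$meta
  if (is.null(scans) || is.null(meta)) {
    abort("`study` must carry `scans` and `meta`.", class = "coinet_bad_argument")
  }
  nodes <- colnames(scans[[1]])
  k <- length(nodes)
  ut <- which(upper.tri(diag(k)), arr.ind = TRUE)
  ut <- ut[order(ut[, "row"], ut[, "col"]), , drop = FALSE]
  conns <- all_connections(nodes)

  per_scan <- lapply(meta$scan_id, function(id) {
    ts <- scans[[id]]
    r <- partial_correlation(ts, ridge = ridge)
    z <- fisher_z(r, normalize = normalize, t_len = nrow(ts), k = k)
    cbind(r_partial = r[ut], z = z[ut])
  })
  n_conn <- nrow(conns)
  out <- meta[rep(seq_len(nrow(meta)), each = n_conn),
              c("subject", "period", "treatment", "timepoint")]
  vals <- do.call(rbind, per_scan)
  dplyr::bind_cols(
    as_tibble(out),
    conns[rep(seq_len(n_conn), times = nrow(meta)), ],
    tibble(r_partial = vals[, "r_partial"], z = vals[, "z"])
  )
}

#' Write a connectivity table to CSV
#'
#' @param conn Tibble from [connectivity()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(conn, path) {
  readr::write_csv(conn, path)
  invisible(path)
}
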