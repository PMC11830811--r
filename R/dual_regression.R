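# Stage-1 dual regression: extract one time series per region by regressing
# all spatial maps (regions + nuisance + optional intercept) simultaneously
# onto each volume.

#' Extract region time series from 4D data by stage-1 dual regression
#'
#' Solves, for every time frame, the least-squares spatial regression
#' `[region maps | nuisance maps | intercept] . x = volume` and returns the
#' region rows of the solution: the multivariate ("all masks at once")
#' extraction that separates overlapping regions and removes CSF/WM signal,
#' unlike per-mask averaging. Nuisance and intercept coefficients are
#' computed but dropped; each region series is then demeaned (but not
#' variance-normalized — downstream correlation is scale-invariant).
#'
#' @param data 4D array (grid x T) or V x T matrix of voxel data.
#' @param regions A [make_region_set()] / [read_region_set()] object whose
#'   voxel grid matches `data`.
#' @param intercept Include a per-frame global offset column (default TRUE).
#' @param demean Demean each returned region series (default TRUE).
#' @return T x K matrix of region time series (columns named by region).
#' @export
#' @examples
#' rs <- make_region_set(c("A", "B", "C"), voxels_per_region = 4)
#' ts <- matrix(rnorm(60), 20, 3)
#' vol <- simulate_volumes(ts, rs)
#' rec <- extract_timeseries(vol, rs)
extract_timeseries <- function(data, regions, intercept = TRUE, demean = TRUE) {
  stopifnot(inherits(regions, "region_set"))
  v_expected <- nrow(regions$maps)
  if (is.array(data) && length(dim(data)) == 4L) {
    if (prod(dim(data)[1:3]) != v_expected ||
        any(abs(dim(data)[1:3] - regions$dim) > 0)) {
      abort(sprintf("Voxel grid mismatch: data %s vs region set %s.",
                    paste(dim(data)[1:3], collapse = "x"),
                    paste(regions$dim, collapse = "x")),
            class = "coinet_dimension_mismatch")
    }
    y <- matrix(data, nrow = v_expected)
  } else {
    y <- as.matrix(data)
    if (nrow(y) != v_expected) {
      abort(sprintf("Data has %d voxels but the region set has %d.",
                    nrow(y), v_expected),
            class = "coinet_dimension_mismatch")
    }
  }
  x <- cbind(regions$maps, regions$nuisance)
  if (intercept) x <- cbind(x, `(intercept)` = 1)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    abort(paste0("Spatial design matrix is rank deficient; collinear map(s): ",
                 paste(dropped, collapse = ", ")),
          class = "coinet_rank_deficient")
  }
  beta <- qr.coef(qr_x, y)            # (K + 2 [+1]) x T
  k <- ncol(regions$maps)
  ts <- t(beta[seq_len(k), , drop = FALSE])
  colnames(ts) <- regions$labels
  if (demean) ts <- scale(ts, center = TRUE, scale = FALSE)[, , drop = FALSE]
  t_len <- nrow(ts)
  if (t_len < k + 5) {
    warn(sprintf("Only %d frames for %d regions; partial correlation needs T >= K+5.",
                 t_len, k))
  }
  ts
}
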