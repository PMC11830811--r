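# Synthetic region sets and 4D volume simulation (fixtures for the
# dual-regression stage).

#' Build a synthetic region set (spatial weight maps)
#'
#' Lays out one rectangular weight blob per region on a small 3D grid, plus
#' CSF and WM nuisance maps, mimicking the mask inputs of the real pipeline.
#' Blobs are disjoint by default; `overlap > 0` bleeds each blob into its
#' neighbour to exercise the joint-regression (rather than mask-averaging)
#' behaviour of stage-1 dual regression.
#'
#' @param labels Region labels (default [clipst_nodes()]).
#' @param voxels_per_region Voxels in each region blob (default 8).
#' @param overlap Fraction (0 to <1) of each blob's weight bled into the
#'   next region's voxels (default 0).
#' @param weight Peak weight value (default 1).
#' @return Object of class `region_set`: list with `labels`, `maps`
#'   (V x K weight matrix), `nuisance` (V x 2, columns CSF and WM), `dim`
#'   (3D grid dimensions) and `affine` (4 x 4, identity grid-to-world).
#' @export
make_region_set <- function(labels = clipst_nodes(), voxels_per_region = 8,
                            overlap = 0, weight = 1) {
  k <- length(labels)
  if (overlap < 0 || overlap >= 1) {
    abort("`overlap` must be in [0, 1).", class = "coinet_bad_argument")
  }
  # one row of background voxels keeps the maps from tiling the grid, so an
  # intercept column stays identifiable
  n_blobs <- k + 2L  # regions + CSF + WM
  v <- (n_blobs + 1L) * voxels_per_region
  dim3 <- c(voxels_per_region, n_blobs + 1L, 1L)
  maps <- matrix(0, v, k, dimnames = list(NULL, labels))
  nuisance <- matrix(0, v, 2, dimnames = list(NULL, c("CSF", "WM")))
  blob <- function(b) seq.int((b - 1L) * voxels_per_region + 1L, b * voxels_per_region)
  for (j in seq_len(k)) {
    maps[blob(j), j] <- weight
    if (overlap > 0) {
      nxt <- if (j < k) j + 1L else 1L
      maps[blob(nxt), j] <- maps[blob(nxt), j] + weight * overlap
    }
  }
  nuisance[blob(k + 1L), "CSF"] <- weight
  nuisance[blob(k + 2L), "WM"] <- weight
  structure(list(labels = labels, maps = maps, nuisance = nuisance,
                 dim = dim3, affine = diag(4)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions + %d nuisance maps over %d voxels (grid %s)\n",
              ncol(x$maps), ncol(x$nuisance), nrow(x$maps),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Simulate 4D volumes from ROI time series
#'
#' Builds voxel data as the spatial mixture
#' `Y[v, t] = sum_k maps[v, k] * ts[t, k] + nuisance contributions + noise`,
#' the forward model that stage-1 dual regression inverts.
#'
#' @param ts T x K matrix of region time series (columns in region-set
#'   order).
#' @param regions A [make_region_set()] object.
#' @param nuisance_ts Optional T x 2 matrix of CSF/WM time series.
#' @param noise_sd Gaussian voxel noise SD (default 0).
#' @param seed Integer seed for the noise draw.
#' @return 4D array with dimensions `c(regions$dim, T)`.
#' @export
simulate_volumes <- function(ts, regions, nuisance_ts = NULL, noise_sd = 0,
                             seed = NULL) {
  stopifnot(inherits(regions, "region_set"))
  ts <- as.matrix(ts)
  if (ncol(ts) != ncol(regions$maps)) {
    abort(sprintf("`ts` has %d columns but the region set has %d regions.",
                  ncol(ts), ncol(regions$maps)),
          class = "coinet_dimension_mismatch")
  }
  y <- regions$maps %*% t(ts)  # V x T
  if (!is.null(nuisance_ts)) {
    nuisance_ts <- as.matrix(nuisance_ts)
    if (nrow(nuisance_ts) != nrow(ts) || ncol(nuisance_ts) != ncol(regions$nuisance)) {
      abort("`nuisance_ts` must be T x 2 (CSF, WM).",
            class = "coinet_dimension_mismatch")
    }
    y <- y + regions$nuisance %*% t(nuisance_ts)
  }
  if (noise_sd > 0) {
    y <- y + with_seed_or_global(seed, matrix(rnorm(length(y), 0, noise_sd), nrow(y)))
  }
  array(y, dim = c(regions$dim, nrow(ts)))
}

#' Write a region set as NIfTI masks with a JSON manifest
#'
#' One 3D weight map per region plus CSF and WM maps, written as `.nii.gz`,
#' and a `manifest.json` naming the files in region order.
#'
#' @param regions A `region_set`.
#' @param dir Output directory.
#' @return Path to the manifest, invisibly.
#' @export
write_region_set <- function(regions, dir) {
  stopifnot(inherits(regions, "region_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map <- function(w, file) {
    img <- RNifti::asNifti(array(w, dim = regions$dim))
    RNifti::writeNifti(img, file.path(dir, file))
    file
  }
  region_files <- vapply(seq_along(regions$labels), function(j) {
    write_map(regions$maps[, j], sprintf("region_%02d_%s.nii.gz", j, regions$labels[j]))
  }, character(1))
  nuis_files <- c(write_map(regions$nuisance[, 1], "nuisance_csf.nii.gz"),
                  write_map(regions$nuisance[, 2], "nuisance_wm.nii.gz"))
  manifest <- list(labels = regions$labels, dim = regions$dim,
                   regions = region_files,
                   nuisance = list(CSF = nuis_files[1], WM = nuis_files[2]))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a region set from a NIfTI mask manifest
#'
#' @param manifest Path to a `manifest.json` written by [write_region_set()]
#'   (or hand-written in the same layout).
#' @return A `region_set` object.
#' @export
read_region_set <- function(manifest) {
  def <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  read_map <- function(file) {
    img <- RNifti::readNifti(file.path(dir, file))
    as.numeric(img)
  }
  maps <- vapply(def$regions, read_map, numeric(prod(def$dim)))
  colnames(maps) <- def$labels
  nuisance <- cbind(CSF = read_map(def$nuisance$CSF), WM = read_map(def$nuisance$WM))
  structure(list(labels = def$labels, maps = maps, nuisance = nuisance,
                 dim = as.integer(def$dim), affine = diag(4)),
            class = "region_set")
}

#' Write a 4D array as NIfTI
#'
#' @param data 4D array (e.g. from [simulate_volumes()]).
#' @param path Output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volumes <- function(data, path) {
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}

#' Read a 4D NIfTI scan
#'
#' @param path A `.nii` / `.nii.gz` file.
#' @return 4D array.
#' @export
read_volumes <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L) {
    abort("Expected a 4D NIfTI image.", class = "coinet_io_error")
  }
  arr
}
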