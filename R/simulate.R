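# Synthetic cross-over study generator.

#' Specify treatment effects on connectivity
#'
#' Effects are expressed on the Fisher-z partial-correlation scale (the
#' analysis scale): for each listed edge the ground-truth partial
#' correlation r becomes `tanh(atanh(r) + delta_z)` in the affected scans.
#' `phase` controls which post-dose scans of the active-treatment period
#' carry the effect: `"acute"` (50/80/165-min scans), `"delayed"` (24-h
#' scan) or `"both"`.
#'
#' @param region_i,region_j Region labels of the affected connections.
#' @param delta_z Signed effect sizes on the Fisher-z scale.
#' @param phase One of `"acute"`, `"delayed"`, `"both"` (recycled).
#' @return Tibble of class `effect_spec` with one row per affected edge.
#' @export
#' @examples
#' effect_spec("vmPFC", "NAcc", delta_z = 1.0, phase = "acute")
effect_spec <- function(region_i, region_j, delta_z,
                        phase = c("acute", "delayed", "both")) {
  if (is.character(phase) && length(phase) == 1L) {
    phase <- match.arg(phase)
  } else {
    bad <- setdiff(phase, c("acute", "delayed", "both"))
    if (length(bad)) {
      abort("`phase` must be 'acute', 'delayed' or 'both'.",
            class = "coinet_bad_argument")
    }
  }
  out <- tibble(region_i = region_i, region_j = region_j,
                delta_z = delta_z, phase = phase)
  if (!all(is.finite(out$delta_z))) {
    abort("`delta_z` must be finite.", class = "coinet_bad_argument")
  }
  if (any(out$region_i == out$region_j)) {
    abort("Effects must link two distinct regions.", class = "coinet_bad_argument")
  }
  class(out) <- c("effect_spec", class(out))
  out
}

#' Cross-over study design
#'
#' Encodes the two-period, two-treatment cross-over layout: each subject
#' receives both treatments, one per period, with treatment order balanced
#' across subjects (odd-numbered subjects receive the active treatment in
#' period 1). Each period has one baseline scan and four post-dose scans.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param t_per_scan Time points per scan (default 220).
#' @param tr Repetition time in seconds (default 2.34); metadata only.
#' @param treatments Length-2 character vector, active treatment first.
#' @return Object of class `study_design`: list with `n_subjects`,
#'   `t_per_scan`, `tr`, `treatments`, `timepoints`, and `sheet` (tibble
#'   subject x period x treatment).
#' @export
study_design <- function(n_subjects = 16, t_per_scan = 220, tr = 2.34,
                         treatments = c("ketamine", "placebo")) {
  stopifnot_scalar_number(n_subjects, "n_subjects")
  stopifnot_scalar_number(t_per_scan, "t_per_scan")
  if (n_subjects < 2) {
    abort("`n_subjects` must be at least 2.", class = "coinet_bad_argument")
  }
  if (length(treatments) != 2L || anyDuplicated(treatments)) {
    abort("`treatments` must be two distinct labels.", class = "coinet_bad_argument")
  }
  subjects <- seq_len(n_subjects)
  active_first <- subjects %% 2L == 1L  # balanced: ceiling(n/2) active in period 1
  sheet <- tibble(
    subject = rep(subjects, each = 2L),
    period = rep(1:2, n_subjects),
    treatment = as.vector(vapply(active_first, function(a) {
      if (a) treatments else rev(treatments)
    }, character(2)))
  )
  structure(
    list(n_subjects = as.integer(n_subjects),
         t_per_scan = as.integer(t_per_scan),
         tr = tr,
         treatments = treatments,
         timepoints = c("baseline", "post50min", "post80min", "post165min", "post24h"),
         sheet = sheet),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d subjects, 2 periods (%s), %d timepoints/period, T=%d, TR=%gs\n",
              x$n_subjects, paste(x$treatments, collapse = " vs "),
              length(x$timepoints), x$t_per_scan, x$tr))
  invisible(x)
}

# Timepoints carrying an effect of a given phase.
acute_timepoints <- function() c("post50min", "post80min", "post165min")
delayed_timepoints <- function() "post24h"

# Draw T x K rows from the zero-mean Gaussian graphical model with the given
# precision matrix; optional stationary AR(1) on each latent series.
rmvn_precision <- function(n, precision, ar = 0) {
  k <- nrow(precision)
  sigma <- chol2inv(chol(precision))
  l <- chol(sigma)
  e <- matrix(rnorm(n * k), n, k)
  if (ar > 0) {
    scale <- sqrt(1 - ar^2)
    for (t in 2:n) e[t, ] <- ar * e[t - 1L, ] + scale * e[t, ]
  }
  x <- e %*% l
  colnames(x) <- rownames(precision)
  x
}

#' Simulate one scan from a ground-truth network
#'
#' Draws a T x K multivariate-normal time series whose precision matrix is
#' the ground truth's, after applying any treatment effect on the
#' partial-correlation scale (followed by positive-definiteness repair).
#' Columns are left on their natural scale (no standardization).
#'
#' @param gt A `gt_network` from [make_ground_truth()].
#' @param effect Optional [effect_spec()] rows to apply to this scan
#'   (all rows are applied regardless of their `phase`; phase routing is
#'   done by [simulate_study()]).
#' @param t_len Number of time points (default 220); must be at least K+5.
#' @param seed Integer seed; `NULL` consumes the global RNG stream.
#' @param ar Optional AR(1) coefficient for temporal autocorrelation
#'   (default 0, i.e. temporally white).
#' @return T x K numeric matrix with region column names.
#' @export
#' @examples
#' gt <- default_ground_truth()
#' ts <- simulate_scan(gt, t_len = 220, seed = 1)
#' dim(ts)
simulate_scan <- function(gt, effect = NULL, t_len = 220, seed = NULL, ar = 0) {
  stopifnot(inherits(gt, "gt_network"))
  k <- length(gt$nodes)
  if (t_len < k + 5) {
    abort(sprintf("`t_len` must be at least K+5 = %d.", k + 5),
          class = "coinet_bad_argument")
  }
  gt_eff <- apply_effect(gt, effect)
  with_seed_or_global(seed, rmvn_precision(t_len, gt_eff$precision, ar = ar))
}

#' Simulate a full cross-over study
#'
#' Generates one scan per subject x period x timepoint. Subject
#' heterogeneity is injected by perturbing each ground-truth edge's partial
#' correlation once per subject with N(0, `subject_sd`^2) noise on the r
#' scale; the perturbed network is shared by all of that subject's scans,
#' which is what makes the paired cross-over contrast informative.
#' Treatment effects apply only to post-dose scans of the active-treatment
#' period: `phase = "acute"` edges to the 50/80/165-min scans,
#' `phase = "delayed"` edges to the 24-h scan, `"both"` to all four.
#'
#' @param design A [study_design()].
#' @param gt Population ground-truth network ([make_ground_truth()]).
#' @param effect Optional [effect_spec()].
#' @param seed Integer root seed; all subject/scan substreams derive from it.
#' @param subject_sd Per-subject edge jitter SD on the r scale (default 0.05).
#' @param ar AR(1) coefficient passed to [simulate_scan()] (default 0).
#' @return Object of class `crossover_study`: list with `scans` (named list
#'   of T x K matrices), `meta` (tibble: scan_id, subject, period, treatment,
#'   timepoint, effect_applied), `design`, `gt`, `effect`, `seed`,
#'   `networks` (per-subject gt_network list).
#' @export
simulate_study <- function(design = study_design(), gt = default_ground_truth(),
                           effect = NULL, seed = 1, subject_sd = 0.05, ar = 0) {
  stopifnot(inherits(design, "study_design"), inherits(gt, "gt_network"))
  if (!is.null(effect)) {
    check_edge_frame(effect, gt$nodes, "delta_z")
  }
  active <- design$treatments[1]
  tps <- design$timepoints

  networks <- vector("list", design$n_subjects)
  scans <- list()
  meta <- list()
  for (s in seq_len(design$n_subjects)) {
    gt_s <- if (subject_sd > 0 && nrow(gt$edges)) {
      make_ground_truth(gt$edges[, c("region_i", "region_j", "r")],
                        nodes = gt$nodes, jitter = subject_sd,
                        seed = derive_seed(seed, "subject-jitter", s))
    } else {
      gt
    }
    networks[[s]] <- gt_s
    sheet_s <- design$sheet[design$sheet$subject == s, ]
    for (row in seq_len(nrow(sheet_s))) {
      p <- sheet_s$period[row]
      trt <- sheet_s$treatment[row]
      for (tp in tps) {
        eff_here <- NULL
        if (!is.null(effect) && trt == active && tp != "baseline") {
          want <- if (tp %in% acute_timepoints()) {
            effect$phase %in% c("acute", "both")
          } else {
            effect$phase %in% c("delayed", "both")
          }
          if (any(want)) eff_here <- effect[want, , drop = FALSE]
        }
        scan_id <- sprintf("S%02d_P%d_%s_%s", s, p, trt, tp)
        scans[[scan_id]] <- simulate_scan(
          gt_s, effect = eff_here, t_len = design$t_per_scan,
          seed = derive_seed(seed, scan_id), ar = ar
        )
        meta[[scan_id]] <- tibble(
          scan_id = scan_id, subject = s, period = p, treatment = trt,
          timepoint = tp, effect_applied = !is.null(eff_here)
        )
      }
    }
  }
  structure(
    list(scans = scans, meta = dplyr::bind_rows(meta), design = design,
         gt = gt, effect = effect, seed = seed, networks = networks,
         subject_sd = subject_sd),
    class = "crossover_study"
  )
}

#' @export
print.crossover_study <- function(x, ...) {
  cat(sprintf("<crossover_study> %d scans (%d subjects x 2 periods x %d timepoints), T=%d, K=%d, seed=%s\n",
              length(x$scans), x$design$n_subjects, length(x$design$timepoints),
              x$design$t_per_scan, length(x$gt$nodes), format(x$seed)))
  invisible(x)
}

#' @export
as_tibble.crossover_study <- function(x, ...) {
  purrr::map2_dfr(x$scans, x$meta$scan_id, function(m, id) {
    info <- x$meta[x$meta$scan_id == id, ]
    dplyr::bind_cols(
      tibble(subject = info$subject, period = info$period,
             treatment = info$treatment, timepoint = info$timepoint,
             frame = seq_len(nrow(m))),
      as_tibble(m)
    )
  })
}

#' Write a simulated study to the tidy CSV dialect
#'
#' Writes `timeseries.csv` (subject, period, treatment, timepoint, frame,
#' one column per region), `design.csv` (the design sheet) and
#' `ground_truth.json` (node names, edge list, effect spec, seed).
#'
#' @param study A `crossover_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "crossover_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(study), file.path(dir, "timeseries.csv"))
  readr::write_csv(study$design$sheet, file.path(dir, "design.csv"))
  gt_json <- list(
    nodes = study$gt$nodes,
    edges = if (nrow(study$gt$edges)) {
      study$gt$edges[, c("region_i", "region_j", "r")]
    } else {
      list()
    },
    effect = if (!is.null(study$effect)) study$effect else list(),
    seed = study$seed,
    subject_sd = study$subject_sd,
    t_per_scan = study$design$t_per_scan
  )
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a tidy time-series CSV into scan matrices
#'
#' Inverse of the `timeseries.csv` written by [write_study()]; also the
#' entry point for real ROI time-series tables in the same dialect.
#'
#' @param path CSV with columns subject, period, treatment, timepoint,
#'   frame, then one column per region.
#' @return List with `scans` (named list of T x K matrices) and `meta`
#'   (tibble of scan metadata), the same layout [connectivity()] accepts.
#' @export
read_timeseries_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  id_cols <- c("subject", "period", "treatment", "timepoint", "frame")
  miss <- setdiff(id_cols, names(df))
  if (length(miss)) {
    abort(paste0("Time-series CSV missing column(s): ", paste(miss, collapse = ", ")),
          class = "coinet_io_error")
  }
  regions <- setdiff(names(df), id_cols)
  df <- dplyr::arrange(df, .data$subject, .data$period, .data$timepoint, .data$frame)
  keys <- dplyr::distinct(df[, c("subject", "period", "treatment", "timepoint")])
  keys$subject <- as.integer(keys$subject)
  keys$period <- as.integer(keys$period)
  keys$scan_id <- sprintf("S%02d_P%d_%s_%s", keys$subject, keys$period,
                          keys$treatment, keys$timepoint)
  scans <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- dplyr::semi_join(df, keys[i, 1:4],
                            by = c("subject", "period", "treatment", "timepoint"))
    as.matrix(sub[order(sub$frame), regions, drop = FALSE])
  })
  names(scans) <- keys$scan_id
  list(scans = scans,
       meta = dplyr::relocate(keys, "scan_id"))
}
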