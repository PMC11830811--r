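# Baseline-corrected cross-over contrasts with per-connection paired t-tests.

#' Baseline-correct a post-dose connectivity score
#'
#' Subtracts the same period's pre-dose (baseline) scan value from a
#' post-dose value, removing stable within-period offsets before the
#' between-treatment contrast.
#'
#' @param z_post,z_baseline Finite numeric values (vectorized).
#' @return `z_post - z_baseline`.
#' @export
#' @examples
#' baseline_correct(1.2, 0.2)  # 1.0
baseline_correct <- function(z_post, z_baseline) {
  if (any(!is.finite(z_post)) || any(!is.finite(z_baseline))) {
    abort("Baseline correction requires finite values.",
          class = "coinet_bad_argument")
  }
  z_post - z_baseline
}

#' Pool the three acute post-dose scores
#'
#' The acute phase contributes three post-dose scans (50, 80 and 165 min);
#' pooling is their arithmetic mean, giving one acute value per subject and
#' treatment (hence the paired t-test's n-1 degrees of freedom).
#'
#' @param z50,z80,z165 Baseline-corrected values (vectorized).
#' @return Elementwise mean of the three inputs.
#' @export
#' @examples
#' pool_acute(1, 2, 3)  # 2
pool_acute <- function(z50, z80, z165) {
  if (any(!is.finite(c(z50, z80, z165)))) {
    abort("Pooling requires three finite values.", class = "coinet_bad_argument")
  }
  (z50 + z80 + z165) / 3
}

# Vectorized paired t statistics: ket and pla are n x m matrices (subjects
# by connections). Returns list(t, df, p, mean_d, sd_d).
paired_t_matrix <- function(ket, pla) {
  d <- ket - pla
  n <- nrow(d)
  mean_d <- unname(colMeans(d))
  sd_d <- unname(sqrt(colSums(sweep(d, 2, mean_d)^2) / (n - 1)))
  t_stat <- mean_d / (sd_d / sqrt(n))
  df <- n - 1
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  list(t = t_stat, df = df, p = p, mean_d = mean_d, sd_d = sd_d, n = n)
}

#' Paired t-test for one connection
#'
#' Classical paired t-test of active vs control values paired by subject:
#' with `d = ket - pla`, `t = mean(d) / (sd(d) / sqrt(n))` (sample SD,
#' n-1 denominator), `df = n - 1`, two-sided Student p-value.
#'
#' @param ket,pla Numeric vectors of per-subject values, same order and
#'   length (n >= 3).
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `sd_diff`, `n`.
#' @export
#' @examples
#' paired_ttest(c(2, 3, 4, 5), c(1, 1, 1, 1))
paired_ttest <- function(ket, pla) {
  if (length(ket) != length(pla)) {
    abort("`ket` and `pla` must pair one value per subject.",
          class = "coinet_bad_argument")
  }
  n <- length(ket)
  if (n < 3) {
    abort("Paired t-test needs at least 3 subjects.", class = "coinet_bad_argument")
  }
  if (any(!is.finite(ket)) || any(!is.finite(pla))) {
    abort("Paired t-test requires finite values.", class = "coinet_bad_argument")
  }
  res <- paired_t_matrix(cbind(ket), cbind(pla))
  if (res$sd_d == 0) {
    abort("All paired differences are identical (zero variance).",
          class = "coinet_degenerate")
  }
  tibble(t = res$t, df = res$df, p = res$p,
         mean_diff = res$mean_d, sd_diff = res$sd_d, n = n)
}

#' Per-connection baseline-corrected treatment contrasts
#'
#' For every connection and phase: (1) baseline-correct each post-dose z
#' by the same period's baseline scan; (2) pool the three acute scans by
#' their mean (the 24-h scan alone is the delayed value); (3) paired
#' t-test of active vs control across subjects. Subjects missing any scan
#' required by a phase are dropped listwise for that phase (with a
#' message).
#'
#' @param conn Long connectivity table from [connectivity()]: columns
#'   `subject`, `period`, `treatment`, `timepoint`, `region_i`, `region_j`,
#'   `z` (and optionally `connection`).
#' @param active Label of the active treatment (default `"ketamine"`);
#'   the other label present is taken as control.
#' @return Tibble with one row per connection x phase: `region_i`,
#'   `region_j`, `connection`, `phase`, `t`, `df`, `p`, `mean_ket`,
#'   `sd_ket`, `mean_pla`, `sd_pla`, `n` — per-condition summaries are of
#'   the baseline-corrected (pooled) z per subject.
#' @export
run_contrasts <- function(conn, active = "ketamine") {
  conn <- as_tibble(conn)
  need <- c("subject", "period", "treatment", "timepoint",
            "region_i", "region_j", "z")
  miss <- setdiff(need, names(conn))
  if (length(miss)) {
    abort(paste0("`conn` missing column(s): ", paste(miss, collapse = ", ")),
          class = "coinet_bad_argument")
  }
  trts <- unique(conn$treatment)
  if (!active %in% trts || length(trts) != 2L) {
    abort("`conn` must contain exactly two treatments including `active`.",
          class = "coinet_bad_argument")
  }
  control <- setdiff(trts, active)
  if (!"connection" %in% names(conn)) {
    nodes <- unique(c(conn$region_i, conn$region_j))
    conn$connection <- connection_key(conn$region_i, conn$region_j, nodes)
  }

  # wide per subject x treatment x connection: baseline, 3 acute, delayed
  wide <- tidyr::pivot_wider(
    conn[, c("subject", "treatment", "timepoint", "connection", "z")],
    names_from = "timepoint", values_from = "z"
  )
  tp_names <- c("baseline", acute_timepoints(), delayed_timepoints())
  have <- intersect(tp_names, names(wide))
  if (!"baseline" %in% have) {
    abort("No baseline scans present.", class = "coinet_bad_argument")
  }

  conn_lookup <- dplyr::distinct(conn[, c("connection", "region_i", "region_j")])

  phase_results <- function(values_by_subj, phase_label) {
    # values_by_subj: tibble subject, connection, ket, pla (corrected values)
    complete <- !is.na(values_by_subj$ket) & !is.na(values_by_subj$pla)
    bad_subj <- unique(values_by_subj$subject[!complete])
    if (length(bad_subj)) {
      rlang::inform(paste0("Dropping subject(s) with incomplete ", phase_label,
                           " scans: ", paste(bad_subj, collapse = ", ")))
      values_by_subj <- values_by_subj[!values_by_subj$subject %in% bad_subj, ]
    }
    ket_m <- tidyr::pivot_wider(values_by_subj[, c("subject", "connection", "ket")],
                                names_from = "connection", values_from = "ket")
    pla_m <- tidyr::pivot_wider(values_by_subj[, c("subject", "connection", "pla")],
                                names_from = "connection", values_from = "pla")
    conns <- setdiff(names(ket_m), "subject")
    km <- as.matrix(ket_m[, conns])
    pm <- as.matrix(pla_m[, conns])
    if (nrow(km) < 3) {
      abort(paste0("Fewer than 3 complete subjects for the ", phase_label, " phase."),
            class = "coinet_bad_argument")
    }
    res <- paired_t_matrix(km, pm)
    if (any(res$sd_d == 0)) {
      bad <- conns[res$sd_d == 0]
      abort(paste0("Zero-variance paired differences for connection(s): ",
                   paste(bad, collapse = ", ")),
            class = "coinet_degenerate")
    }
    tibble(
      connection = conns, phase = phase_label,
      t = res$t, df = res$df, p = res$p,
      mean_ket = unname(colMeans(km)), sd_ket = unname(apply(km, 2, sd)),
      mean_pla = unname(colMeans(pm)), sd_pla = unname(apply(pm, 2, sd)),
      n = res$n
    )
  }

  corrected <- function(tp) {
    if (!tp %in% names(wide)) return(rep(NA_real_, nrow(wide))) # nocov
    wide[[tp]] - wide$baseline
  }
  acute_vals <- (corrected("post50min") + corrected("post80min") +
                   corrected("post165min")) / 3
  delayed_vals <- corrected("post24h")

  per_trt <- tibble(subject = wide$subject, treatment = wide$treatment,
                    connection = wide$connection,
                    acute = acute_vals, delayed = delayed_vals)
  split_trt <- function(col) {
    ket <- per_trt[per_trt$treatment == active, c("subject", "connection", col)]
    pla <- per_trt[per_trt$treatment == control, c("subject", "connection", col)]
    names(ket)[3] <- "ket"
    names(pla)[3] <- "pla"
    dplyr::full_join(ket, pla, by = c("subject", "connection"))
  }

  out <- dplyr::bind_rows(
    phase_results(split_trt("acute"), "acute"),
    phase_results(split_trt("delayed"), "delayed")
  )
  out <- dplyr::left_join(out, conn_lookup, by = "connection")
  dplyr::relocate(out, "region_i", "region_j", "connection", "phase")
}

#' Write contrast results to CSV
#'
#' @param results Tibble from [run_contrasts()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contrasts <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}
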