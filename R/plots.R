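# ggplot2 displays for connectivity, the COI grid, and PK profiles.

#' Heatmap of mean connectivity z scores
#'
#' Averages the Fisher-z partial correlations over scans (optionally within
#' a treatment/timepoint subset made upstream with dplyr) and draws the
#' K x K half-matrix.
#'
#' @param conn Long connectivity tibble from [connectivity()].
#' @param nodes Region ordering (default [clipst_nodes()]).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(conn, nodes = clipst_nodes()) {
  means <- dplyr::summarise(
    dplyr::group_by(as_tibble(conn), .data$region_i, .data$region_j),
    z = mean(.data$z), .groups = "drop"
  )
  means$region_i <- factor(means$region_i, levels = nodes)
  means$region_j <- factor(means$region_j, levels = rev(nodes))
  ggplot2::ggplot(means, ggplot2::aes(.data$region_i, .data$region_j,
                                      fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean z",
                  title = "Mean partial-correlation connectivity (Fisher z)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a COI grid, optionally with test results
#'
#' Upper-triangle tile plot of all region pairs: connections of interest
#' shaded, significant connections (when `results` is given) outlined.
#'
#' @param grid A [coi_grid()].
#' @param results Optional contrast results with `region_i`, `region_j`,
#'   `phase`, `p` (e.g. from [run_contrasts()]); facets by phase.
#' @param alpha Significance threshold used for outlining (default 0.05).
#' @return A ggplot object.
#' @export
plot_coi_grid <- function(grid, results = NULL, alpha = 0.05) {
  stopifnot(inherits(grid, "coi_grid"))
  cells <- grid$all
  cells$region_i <- factor(cells$region_i, levels = grid$nodes)
  cells$region_j <- factor(cells$region_j, levels = grid$nodes)
  p <- ggplot2::ggplot(cells, ggplot2::aes(.data$region_j, .data$region_i)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$is_coi), color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#9ECAE1", `FALSE` = "white"),
                               labels = c(`TRUE` = "COI", `FALSE` = "other"),
                               name = NULL) +
    ggplot2::scale_y_discrete(limits = rev(grid$nodes)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Connection-of-interest grid") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(results)) {
    res <- as_tibble(results)
    res$connection <- connection_key(res$region_i, res$region_j, grid$nodes)
    sig <- dplyr::left_join(res[res$p < alpha, ],
                            grid$all[, c("connection", "region_i", "region_j")],
                            by = "connection", suffix = c(".drop", ""))
    if (nrow(sig)) {
      sig$region_i <- factor(sig$region_i, levels = grid$nodes)
      sig$region_j <- factor(sig$region_j, levels = grid$nodes)
      p <- p + ggplot2::geom_tile(data = sig, fill = NA, color = "#B2182B",
                                  linewidth = 1) +
        ggplot2::facet_wrap(~phase)
    }
  }
  p
}

#' Concentration-time plot for PK profiles
#'
#' @param profiles Tibble of profiles (columns `time_min`,
#'   `conc_ng_per_ml`, optionally `subject`, `analyte`).
#' @param log_y Use a log10 concentration axis (default FALSE); zero
#'   concentrations are dropped from a log plot.
#' @return A ggplot object.
#' @export
plot_pk_profile <- function(profiles, log_y = FALSE) {
  df <- as_tibble(profiles)
  if (!"analyte" %in% names(df)) df$analyte <- "analyte"
  if (!"subject" %in% names(df)) df$subject <- 1L
  if (log_y) df <- df[df$conc_ng_per_ml > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_min / 60,
                                        .data$conc_ng_per_ml,
                                        color = .data$analyte,
                                        group = interaction(.data$subject,
                                                            .data$analyte))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (h)", y = "concentration (ng/ml)", color = NULL,
                  title = "Concentration-time profiles") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn enrichment_test Bar display of significant counts inside and
#'   outside the COI set per phase, annotated with the exact p-value.
#' @param object A `coi_enrichment` object.
#' @export
autoplot.coi_enrichment <- function(object, ...) {
  tb <- tidy(object)
  long <- dplyr::bind_rows(
    tibble(phase = tb$phase, set = sprintf("COI (n=%d)", tb$n_in),
           significant = tb$k_in),
    tibble(phase = tb$phase, set = sprintf("non-COI (n=%d)", tb$n_out),
           significant = tb$k_out)
  )
  labels <- tibble(phase = tb$phase,
                   label = sprintf("p = %.4f", tb$p_exact),
                   y = max(long$significant) + 0.5)
  ggplot2::ggplot(long, ggplot2::aes(.data$set, .data$significant,
                                     fill = .data$set)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(data = labels, inherit.aes = FALSE,
                       ggplot2::aes(x = 1.5, y = .data$y, label = .data$label)) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::scale_fill_manual(values = c("#9ECAE1", "grey85")) +
    ggplot2::labs(x = NULL, y = "significant connections",
                  title = "COI enrichment of significant effects") +
    ggplot2::theme_minimal()
}
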