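# ggplot2 views of the main result types.

#' Plot a cophenetic rank-selection profile
#'
#' @param x A `rank_selection` from [select_rank()].
#' @return A ggplot.
#' @export
plot_rank_profile <- function(x) {
  ggplot2::ggplot(x$profile, ggplot2::aes(x = .data$rank,
                                          y = .data$cophenetic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$best_rank, linetype = "dashed") +
    ggplot2::labs(x = "factorization rank", y = "cophenetic coefficient") +
    ggplot2::theme_minimal()
}

#' Volcano plot of per-cluster differential expression
#'
#' @param de Tibble from [differential_expression()].
#' @param alpha,fc_min Thresholds used for colouring.
#' @return A ggplot, faceted by cluster.
#' @export
plot_volcano <- function(de, alpha = 0.05, fc_min = 1) {
  de <- mutate(de, status = dplyr::case_when(
    .data$significant_high ~ "up",
    .data$significant_low ~ "down",
    TRUE ~ "ns"
  ))
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")
    ) +
    ggplot2::geom_vline(xintercept = c(-fc_min, fc_min), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for risk groups
#'
#' @param km Tibble from [evaluate_risk_model()] (`km` element): `group`,
#'   `time`, `survival`.
#' @return A ggplot of step survival curves.
#' @export
plot_km <- function(km) {
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-target TF regulatory values
#'
#' @param fits `fits` tibble from [infer_cluster_network()].
#' @return A ggplot tile map of R^2 by target and cluster.
#' @export
plot_regulatory_values <- function(fits) {
  ggplot2::ggplot(fits, ggplot2::aes(x = factor(.data$cluster),
                                     y = .data$target,
                                     fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#8e44ad",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "cluster", y = "target gene",
                  fill = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' Time-dependent AUC curve
#'
#' @param auc Tibble from [time_dependent_auc()].
#' @return A ggplot.
#' @export
plot_time_auc <- function(auc) {
  ggplot2::ggplot(filter(auc, !is.na(.data$auc)),
                  ggplot2::aes(x = .data$time, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "AUC(t)") +
    ggplot2::theme_minimal()
}
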