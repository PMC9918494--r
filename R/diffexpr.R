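# Per-cluster differential expression against the normal cohort, and the
# stimulatory/inhibitory signature-gene inclusion rule. Inputs are already
# normalized continuous values, so the test is a Welch t-test on
# log2(x + eps); the inclusion rule operates on the raw-p significance flags.

welch_rows <- function(A, B) {
  # rowwise Welch two-sample t-test between matrices A and B
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- apply(A, 1, var); v2 <- apply(B, 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  list(statistic = tstat, p_value = p, degenerate = degenerate)
}

#' Per-cluster differential expression versus the normal cohort
#'
#' For every (gene, cluster) pair computes `log2fc = log2((mean_cluster +
#' eps) / (mean_normal + eps))` and a Welch two-sample t-test on
#' `log2(x + eps)`, with Benjamini-Hochberg adjustment across genes within
#' each cluster. Significance flags follow the raw p-value threshold, the
#' adjusted p is reported alongside.
#'
#' @param expr Wide expression tibble (`gene_id` + sample columns).
#' @param sample_info Tibble `sample_id`, `cohort` (`tumor`/`normal`) and
#'   `cluster` (integer, `NA` for normals).
#' @param alpha Raw p-value threshold (default 0.05).
#' @param fc_min Absolute log2 fold-change threshold (default 1).
#' @param eps Stabilizing offset for ratios and logs (default 1).
#' @return Tibble with `gene_id`, `cluster`, `log2fc`, `p_value`, `adj_p`,
#'   `significant_high`, `significant_low`.
#' @export
differential_expression <- function(expr, sample_info, alpha = 0.05,
                                    fc_min = 1, eps = 1) {
  m <- as_feature_matrix(expr)
  normals <- sample_info$sample_id[sample_info$cohort == "normal"]
  normals <- intersect(normals, colnames(m))
  if (length(normals) < 2) stop_usage("need >= 2 normal samples")
  clusters <- sort(unique(sample_info$cluster[!is.na(sample_info$cluster)]))
  if (length(clusters) == 0) stop_usage("no cluster labels in sample_info")
  if (any(m + eps <= 0)) {
    stop_usage("expression + eps must be positive for the log-scale test")
  }
  lm_all <- log2(m + eps)
  ln <- lm_all[, normals, drop = FALSE]
  mean_n <- rowMeans(m[, normals, drop = FALSE])

  out <- purrr::map_dfr(clusters, function(cl) {
    samp <- sample_info$sample_id[!is.na(sample_info$cluster) &
                                    sample_info$cluster == cl]
    samp <- intersect(samp, colnames(m))
    if (length(samp) < 2) stop_usage(sprintf("cluster %s has < 2 samples", cl))
    wt <- welch_rows(lm_all[, samp, drop = FALSE], ln)
    if (any(wt$degenerate)) {
      inform(sprintf(
        "cluster %s: %d gene(s) with zero variance in both groups; p set to 1",
        cl, sum(wt$degenerate)
      ))
    }
    log2fc <- log2((rowMeans(m[, samp, drop = FALSE]) + eps) / (mean_n + eps))
    tibble(
      gene_id = rownames(m),
      cluster = as.integer(cl),
      log2fc = unname(log2fc),
      p_value = unname(wt$p_value),
      adj_p = p.adjust(unname(wt$p_value), method = "BH"),
      significant_high = unname(wt$p_value < alpha & log2fc > fc_min),
      significant_low = unname(wt$p_value < alpha & log2fc < -fc_min)
    )
  })
  out
}

#' Select signature genes by the stimulatory/inhibitory rule
#'
#' A stimulatory gene is included iff it is *not* significantly highly
#' expressed in any cluster; an inhibitory gene is included iff it *is*
#' significantly highly expressed in at least one cluster. Genes without a
#' class are dropped with a warning.
#'
#' @param de Differential-expression tibble from
#'   [differential_expression()].
#' @param classes Tibble `gene_id`, `class` with class `stimulatory` or
#'   `inhibitory`.
#' @return Tibble `gene_id`, `class`, `high_in_any`, `included`; the
#'   signature set is `gene_id[included]`.
#' @export
select_signature_genes <- function(de, classes) {
  unknown <- setdiff(unique(de$gene_id), classes$gene_id)
  if (length(unknown) > 0) {
    warn(sprintf("%d gene(s) without a regulator class were excluded",
                 length(unknown)))
  }
  de |>
    group_by(.data$gene_id) |>
    summarise(high_in_any = any(.data$significant_high), .groups = "drop") |>
    inner_join(classes, by = "gene_id") |>
    mutate(included = ifelse(.data$class == "stimulatory",
                             !.data$high_in_any, .data$high_in_any)) |>
    select("gene_id", "class", "high_in_any", "included") |>
    arrange(.data$gene_id)
}
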