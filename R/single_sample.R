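# Single-sample regulatory inference: peak -> gene linking within a TSS
# window, best-peak selection by Spearman correlation, motif-derived TF
# candidates, per-sample deviation calls, sign inference, and
# interaction-score-verified edge assembly.

#' Spearman correlation with t-approximation p-value
#'
#' Rank (average ranks for ties) Pearson correlation; the p-value uses the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))`. Constant
#' input yields `rho = 0`, `p = 1`, flagged degenerate.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return One-row tibble `rho`, `p_value`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_usage("x and y must have equal length")
  if (n < 4) stop_usage("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = 0, p_value = 1, n = n, degenerate = TRUE))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  tibble(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

#' Link peaks to a gene by TSS window overlap
#'
#' Returns peaks whose interval overlaps the symmetric window
#' `[tss - window, tss + window)` on the gene's chromosome, regardless of
#' strand. `distance_to_tss` is the gap between the interval and the TSS
#' (0 if the peak covers it).
#'
#' @param gene One-row tibble with `gene_id`, `chrom`, `tss`.
#' @param peaks A [peak_set()] or a peaks tibble.
#' @param window Half-width of the window in bp (default 20000).
#' @return Tibble `peak_id`, `chrom`, `start`, `end`, `distance_to_tss`.
#' @export
link_peaks_to_gene <- function(gene, peaks, window = 20000) {
  p <- if (inherits(peaks, "peak_set")) peaks$peaks else peaks
  tss <- gene$tss[1]
  p |>
    filter(.data$chrom == gene$chrom[1],
           .data$start < tss + window,
           .data$end > tss - window) |>
    mutate(distance_to_tss = pmax(0L, .data$start - tss, tss - .data$end)) |>
    select("peak_id", "chrom", "start", "end", "distance_to_tss")
}

#' Select the best-correlated peak for a gene
#'
#' Among candidate peaks whose signal correlates with the gene's expression
#' across matched ATAC samples at `p < p_max`, picks the one with the
#' largest `|rho|`; ties break by smaller distance to the TSS, then
#' lexicographic peak id.
#'
#' @param gene_expr Named numeric vector: the gene's expression, names are
#'   sample ids matched to ATAC signal columns.
#' @param peaks A [peak_set()].
#' @param candidates Candidate tibble from [link_peaks_to_gene()].
#' @param p_max Correlation p-value threshold (default 0.01).
#' @return One-row tibble `peak_id`, `distance_to_tss`, `rho`, `p_value`,
#'   or NULL if no candidate passes.
#' @export
select_best_peak <- function(gene_expr, peaks, candidates, p_max = 0.01) {
  stopifnot(inherits(peaks, "peak_set"))
  if (nrow(candidates) == 0) return(NULL)
  sig <- as_feature_matrix(peaks$signal)
  matched <- intersect(names(gene_expr), colnames(sig))
  if (length(matched) == 0) {
    stop_usage("no ATAC samples matched to the expression vector")
  }
  stats <- purrr::map_dfr(candidates$peak_id, function(p) {
    res <- spearman_cor(gene_expr[matched], sig[p, matched])
    mutate(res, peak_id = p)
  })
  stats <- stats |>
    left_join(select(candidates, "peak_id", "distance_to_tss"),
              by = "peak_id") |>
    filter(.data$p_value < p_max) |>
    arrange(dplyr::desc(abs(.data$rho)), .data$distance_to_tss, .data$peak_id)
  if (nrow(stats) == 0) return(NULL)
  select(stats[1, ], "peak_id", "distance_to_tss", "rho", "p_value")
}

#' Single-observation deviation call against a reference cohort
#'
#' Tests one value against a reference distribution with the
#' prediction-variance-inflated one-sample t form: `statistic = (value -
#' mean_ref) / (sd_ref * sqrt(1 + 1/n))`, two-sided p on `n - 1` degrees of
#' freedom. Direction is `high`/`low` only when `p < p_threshold`.
#'
#' @param value Single numeric observation.
#' @param reference Numeric reference vector, length >= 3.
#' @param p_threshold Call threshold (default 0.001).
#' @return One-row tibble `direction`, `statistic`, `p_value`, `degenerate`.
#' @export
single_sample_deviation <- function(value, reference, p_threshold = 0.001) {
  n <- length(reference)
  if (n < 3) stop_usage("reference cohort must have >= 3 values")
  s <- sd(reference)
  if (s == 0) {
    if (value == reference[1]) {
      return(tibble(direction = "normal", statistic = 0, p_value = 1,
                    degenerate = TRUE))
    }
    return(tibble(direction = ifelse(value > reference[1], "high", "low"),
                  statistic = ifelse(value > reference[1], Inf, -Inf),
                  p_value = 0, degenerate = TRUE))
  }
  stat <- (value - mean(reference)) / (s * sqrt(1 + 1 / n))
  p <- 2 * pt(-abs(stat), n - 1)
  dir <- if (p < p_threshold) ifelse(stat > 0, "high", "low") else "normal"
  tibble(direction = dir, statistic = stat, p_value = p, degenerate = FALSE)
}

# Vectorized deviation calls: one row per (feature, sample).
deviation_calls <- function(values, ref, p_threshold) {
  # values: features x samples matrix; ref: features x reference matrix
  n <- ncol(ref)
  mu <- rowMeans(ref)
  s <- apply(ref, 1, sd)
  infl <- sqrt(1 + 1 / n)
  stat <- (values - mu) / (s * infl)
  p <- 2 * pt(-abs(stat), n - 1)
  degenerate <- s == 0
  if (any(degenerate)) {
    for (i in which(degenerate)) {
      eq <- values[i, ] == ref[i, 1]
      stat[i, ] <- ifelse(eq, 0, ifelse(values[i, ] > ref[i, 1], Inf, -Inf))
      p[i, ] <- ifelse(eq, 1, 0)
    }
  }
  dir <- matrix("normal", nrow(values), ncol(values),
                dimnames = dimnames(values))
  dir[p < p_threshold & stat > 0] <- "high"
  dir[p < p_threshold & stat < 0] <- "low"
  list(direction = dir, statistic = stat, p_value = p)
}

#' Infer the regulation sign from three deviation calls
#'
#' Open chromatin is a prerequisite for TF binding, so a call requires the
#' peak signal and the TF expression both high; the target's direction then
#' decides the sign: high means activation (`+`), low means repression
#' (`-`). Every other combination yields `NA` (no call).
#'
#' @param peak_direction,tf_direction,gene_direction Calls in
#'   `c("high", "low", "normal")`; vectorized.
#' @return Character vector of `"+"`, `"-"` or `NA`.
#' @export
infer_regulation_sign <- function(peak_direction, tf_direction,
                                  gene_direction) {
  ok <- c("high", "low", "normal")
  stopifnot(all(peak_direction %in% ok), all(tf_direction %in% ok),
            all(gene_direction %in% ok))
  out <- rep(NA_character_, length(gene_direction))
  open <- peak_direction == "high" & tf_direction == "high"
  out[open & gene_direction == "high"] <- "+"
  out[open & gene_direction == "low"] <- "-"
  out
}

#' Assemble one sample's regulatory network from component calls
#'
#' For each (gene, peak, candidate TF) row, combines the sample's peak, TF
#' and gene deviation calls into a signed edge; edges whose (TF, gene) pair
#' has no interaction score are dropped (the score table acts as a
#' verification filter), surviving edges are weighted by the score and
#' flagged with the validation sets containing the pair.
#'
#' @param sample_id Sample identifier (edge scope).
#' @param candidates Tibble `gene_id`, `peak_id`, `tf`.
#' @param gene_calls,tf_calls Tibbles `id`, `direction`, `p_value` for this
#'   sample.
#' @param peak_calls Tibble `id`, `direction` for this sample's peaks.
#' @param scores Interaction score tibble `tf`, `target`, `score`.
#' @param validation_sets Optional named list of tibbles `tf`, `target`.
#' @return Edge tibble `scope`, `tf`, `target`, `sign`, `weight`,
#'   `p_value`, `evidence`.
#' @export
build_sample_network <- function(sample_id, candidates, gene_calls, tf_calls,
                                 peak_calls, scores,
                                 validation_sets = NULL) {
  if (nrow(candidates) == 0) return(empty_edges())
  df <- candidates |>
    left_join(rename(select(gene_calls, "id", "direction", "p_value"),
                     gene_id = "id", gene_dir = "direction",
                     gene_p = "p_value"),
              by = "gene_id") |>
    left_join(rename(select(tf_calls, "id", "direction"),
                     tf = "id", tf_dir = "direction"),
              by = "tf") |>
    left_join(rename(select(peak_calls, "id", "direction"),
                     peak_id = "id", peak_dir = "direction"),
              by = "peak_id") |>
    filter(!is.na(.data$gene_dir), !is.na(.data$tf_dir),
           !is.na(.data$peak_dir))
  df$sign <- infer_regulation_sign(df$peak_dir, df$tf_dir, df$gene_dir)
  df <- filter(df, !is.na(.data$sign))
  # the score table verifies the pair: unscored candidates are dropped
  df <- inner_join(df, scores, by = c("tf", "gene_id" = "target"))
  if (nrow(df) == 0) return(empty_edges())
  evid <- rep("", nrow(df))
  for (nm in names(validation_sets %||% list())) {
    vs <- validation_sets[[nm]]
    hit <- paste(df$tf, df$gene_id) %in% paste(vs$tf, vs$target)
    evid <- ifelse(hit, ifelse(evid == "", nm, paste(evid, nm, sep = ",")),
                   evid)
  }
  tibble(
    scope = sample_id, tf = df$tf, target = df$gene_id, sign = df$sign,
    weight = df$score, p_value = df$gene_p, evidence = evid
  ) |>
    arrange(.data$target, .data$tf)
}

empty_edges <- function() {
  tibble(scope = character(0), tf = character(0), target = character(0),
         sign = character(0), weight = numeric(0), p_value = numeric(0),
         evidence = character(0))
}

# Leave-one-out deviation calls for peak signal across the ATAC cohort.
peak_deviation_calls <- function(sig, p_threshold) {
  n <- ncol(sig)
  dir <- matrix("normal", nrow(sig), n, dimnames = dimnames(sig))
  for (i in seq_len(nrow(sig))) {
    x <- sig[i, ]
    for (j in seq_len(n)) {
      call <- single_sample_deviation(x[j], x[-j], p_threshold)
      dir[i, j] <- call$direction
    }
  }
  dir
}

#' Per-patient regulatory networks across a cohort
#'
#' Runs the full single-sample framework: links peaks to each immune-related
#' gene within the TSS window, selects the best-correlated peak, derives
#' candidate TFs for that peak (motif scanning of its DNA sequence against a
#' PWM library, or a precomputed peak-to-TF map), calls per-sample
#' deviations of gene expression and TF expression against the normal
#' cohort and of peak signal against the ATAC cohort (leave-one-out), infers
#' edge signs, and keeps score-verified edges.
#'
#' @param expr Wide expression tibble covering genes and TFs.
#' @param sample_info Tibble `sample_id`, `cohort`, `cluster`.
#' @param peaks A [peak_set()].
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param ir_genes Character vector of target genes to analyse.
#' @param scores Interaction score tibble.
#' @param pwms Named list of [pwm()] objects (motif route), or NULL.
#' @param sequences Tibble `peak_id`, `seq` (required with `pwms`).
#' @param peak_tf_map Precomputed tibble `peak_id`, `tf` (alternative to
#'   motif scanning).
#' @param samples Samples to analyse; defaults to ATAC samples present in
#'   the expression table.
#' @param window TSS window half-width (bp).
#' @param p_link Best-peak correlation threshold.
#' @param p_expr Expression deviation threshold (genes and TFs).
#' @param p_peak Peak signal deviation threshold (looser: ATAC cohorts are
#'   small).
#' @param score_fraction Motif hit threshold for [scan_motifs()].
#' @param validation_sets Optional named list of known TF-target tables.
#' @return List with `edges` (all samples pooled), `links` (per-gene best
#'   peak), and `candidates` (gene/peak/TF triples fed to sign inference).
#' @export
single_sample_networks <- function(expr, sample_info, peaks, annotation,
                                   ir_genes, scores, pwms = NULL,
                                   sequences = NULL, peak_tf_map = NULL,
                                   samples = NULL, window = 20000,
                                   p_link = 0.01, p_expr = 0.001,
                                   p_peak = 0.05, score_fraction = 0.8,
                                   validation_sets = NULL) {
  if (is.null(pwms) && is.null(peak_tf_map)) {
    stop_usage("provide either a PWM library (with sequences) or a peak_tf_map")
  }
  m <- as_feature_matrix(expr)
  sig <- as_feature_matrix(peaks$signal)
  normals <- intersect(sample_info$sample_id[sample_info$cohort == "normal"],
                       colnames(m))
  if (length(normals) < 3) stop_usage("need >= 3 normal samples")
  atac_samples <- intersect(colnames(sig), colnames(m))
  if (length(atac_samples) < 4) stop_usage("need >= 4 matched ATAC samples")
  samples <- samples %||% atac_samples
  samples <- intersect(samples, atac_samples)

  ## best peak per gene
  links <- purrr::map_dfr(intersect(ir_genes, rownames(m)), function(g) {
    gene <- filter(annotation, .data$gene_id == g)
    if (nrow(gene) == 0) return(NULL)
    cand <- link_peaks_to_gene(gene, peaks, window)
    best <- select_best_peak(m[g, atac_samples], peaks, cand, p_link)
    if (is.null(best)) return(NULL)
    mutate(best, gene_id = g)
  })
  if (nrow(links) == 0) {
    return(list(edges = empty_edges(), links = links,
                candidates = tibble()))
  }

  ## candidate TFs per selected peak
  if (!is.null(peak_tf_map)) {
    candidates <- inner_join(select(links, "gene_id", "peak_id"),
                             peak_tf_map, by = "peak_id")
  } else {
    stopifnot(!is.null(sequences))
    candidates <- purrr::map_dfr(unique(links$peak_id), function(p) {
      s <- sequences$seq[sequences$peak_id == p][1]
      hit_tfs <- names(pwms)[vapply(pwms, function(w) {
        nrow(scan_motifs(w, s, score_fraction)) > 0
      }, logical(1))]
      if (length(hit_tfs) == 0) return(NULL)
      tibble(peak_id = p, tf = hit_tfs)
    })
    candidates <- inner_join(select(links, "gene_id", "peak_id"),
                             candidates, by = "peak_id")
  }
  candidates <- filter(candidates, .data$tf %in% rownames(m))
  if (nrow(candidates) == 0) {
    return(list(edges = empty_edges(), links = links, candidates = candidates))
  }

  ## deviation calls
  feat <- unique(c(candidates$gene_id, candidates$tf))
  expr_calls <- deviation_calls(m[feat, samples, drop = FALSE],
                                m[feat, normals, drop = FALSE], p_expr)
  peak_dirs <- peak_deviation_calls(
    sig[unique(candidates$peak_id), , drop = FALSE], p_peak
  )

  edges <- purrr::map_dfr(samples, function(s) {
    gene_calls <- tibble(
      id = candidates$gene_id,
      direction = expr_calls$direction[candidates$gene_id, s],
      p_value = expr_calls$p_value[candidates$gene_id, s]
    ) |> distinct()
    tf_calls <- tibble(
      id = unique(candidates$tf),
      direction = expr_calls$direction[unique(candidates$tf), s],
      p_value = expr_calls$p_value[unique(candidates$tf), s]
    )
    pk <- unique(candidates$peak_id)
    peak_calls <- tibble(id = pk, direction = peak_dirs[pk, s])
    build_sample_network(s, candidates, gene_calls, tf_calls, peak_calls,
                         scores, validation_sets)
  })
  list(edges = edges, links = links, candidates = candidates)
}
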