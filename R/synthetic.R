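# Synthetic multi-omics cohort with planted ground truth. Emulates the
# statistical structure the inference stack assumes: a signed TF -> target
# network, chromatin peaks whose signal tracks their target's expression, CNV
# dosage effects, cluster mean-shift subtype structure, sparse per-sample
# TF activation events, and survival times driven by a linear risk score.

#' Simulate a multi-omics cohort with planted regulatory truth
#'
#' Generates matched expression (tumour + normal, positive log2-like scale,
#' baseline 8), ATAC-seq peaks and signal, peak DNA sequences carrying the
#' bound TFs' consensus motifs, gene-level CNV, interaction scores covering
#' every planted pair plus decoys, clinical survival, gene annotation and a
#' motif library, together with the planted truth needed to score recovery.
#'
#' Regulated targets follow `target = baseline + sum(sign * effect * (TF -
#' baseline)) + dosage * CNV + block shift + noise`, with noise scaled so the
#' regulatory signal-to-noise ratio equals `snr`. Each planted TF is
#' activated (shifted by `event_shift`) in a sparse random subset of tumour
#' samples, giving the single-sample framework detectable deviations; each
#' cluster up-shifts a dedicated block of
#' unregulated genes by `cluster_shift`, giving the subtype structure NMF is
#' asked to recover.
#'
#' @param n_tumor,n_normal,n_genes,n_tfs,n_clusters,n_atac,n_peaks Cohort
#'   geometry. Defaults mirror a 1/10-scale TCGA-like cohort: 50 tumours per
#'   cluster, 30 normals, 200 candidate genes, 40 TFs, 20 ATAC samples, 500
#'   peaks.
#' @param n_targets Number of regulated targets carrying planted TF edges.
#' @param snr Ratio of regulatory signal variance to residual noise variance
#'   for regulated targets.
#' @param cluster_shift Mean shift of each cluster's signature block.
#' @param event_shift TF expression shift in activation-event samples.
#' @param event_rate Fraction of tumour samples in which a planted TF is
#'   activated (sample-specific regulatory events).
#' @param dosage CNV dosage coefficient for dosage-affected genes.
#' @param baseline Baseline expression level (log2-like scale).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `immureg_cohort` with elements `expr`,
#'   `sample_info`, `peaks` ([peak_set()]), `sequences`, `pwms`,
#'   `annotation`, `scores`, `cnv`, `survival`, `gene_lists`, and `truth`.
#' @export
simulate_cohort <- function(n_tumor = 200, n_normal = 30, n_genes = 200,
                            n_tfs = 40, n_clusters = 4, n_atac = 20,
                            n_peaks = 500, n_targets = 16, snr = 10,
                            cluster_shift = 3, event_shift = 5,
                            event_rate = 0.1, dosage = 0.5, baseline = 8,
                            seed = 1) {
  if (n_tumor < 4 * n_clusters) stop_usage("need n_tumor >= 4 * n_clusters")
  if (n_atac < 8) stop_usage("need n_atac >= 8")
  if (n_targets > n_genes) stop_usage("n_targets cannot exceed n_genes")
  if (n_peaks < n_targets) stop_usage("need at least one peak per target")
  set.seed(seed)

  genes <- sprintf("G%03d", seq_len(n_genes))
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  tumor_ids <- sprintf("T%03d", seq_len(n_tumor))
  normal_ids <- sprintf("N%03d", seq_len(n_normal))
  clusters <- rep_len(seq_len(n_clusters), n_tumor)
  atac_ids <- tumor_ids[seq_len(n_atac)]  # round-robin: covers all clusters

  sample_info <- bind_rows(
    tibble(sample_id = tumor_ids, cohort = "tumor", cluster = clusters),
    tibble(sample_id = normal_ids, cohort = "normal", cluster = NA_integer_)
  )

  ## planted network ---------------------------------------------------------
  targets <- genes[seq_len(n_targets)]
  n_reg <- pmin(1 + rbinom(n_targets, 2, 0.35), n_tfs)  # 1..3 regulators
  net <- purrr::map2_dfr(targets, n_reg, function(g, k) {
    tibble(
      tf = sample(tfs, k),
      target = g,
      sign = ifelse(runif(k) < 0.7, "+", "-"),
      effect = runif(k, 0.8, 1.5),
      primary = c(TRUE, rep(FALSE, k - 1))
    )
  })
  planted_tfs <- unique(net$tf)

  ## TF expression with sparse per-sample activation events ------------------
  ## events are sample-specific, not subtype-specific: they give the
  ## single-sample framework detectable deviations without adding a coherent
  ## extra cluster to the subtype structure
  tf_tumor <- matrix(rnorm(n_tfs * n_tumor), n_tfs,
                     dimnames = list(tfs, tumor_ids))
  events <- matrix(FALSE, n_tfs, n_tumor, dimnames = list(tfs, tumor_ids))
  for (t_ in planted_tfs) {
    ev <- which(runif(n_tumor) < event_rate)
    events[t_, ev] <- TRUE
    tf_tumor[t_, ev] <- tf_tumor[t_, ev] + event_shift
  }
  tf_normal <- matrix(rnorm(n_tfs * n_normal), n_tfs,
                      dimnames = list(tfs, normal_ids))

  ## CNV (tumour only) -------------------------------------------------------
  cnv_mat <- matrix(rnorm(n_genes * n_tumor), n_genes,
                    dimnames = list(genes, tumor_ids))
  dosage_genes <- c(
    targets[seq_len(min(10, n_targets))],
    genes[seq(n_targets + 1, length.out = min(10, n_genes - n_targets))]
  )
  cnv_effects <- tibble(gene_id = dosage_genes, dosage = dosage)

  ## cluster signature blocks on unregulated genes ---------------------------
  ## per-sample signature strength emulates tumour purity: every cluster has
  ## core samples and boundary samples with a diluted subtype signature
  free_genes <- setdiff(genes, targets)
  block_size <- min(40, floor(length(free_genes) / n_clusters))
  blocks <- tibble(
    gene_id = free_genes[seq_len(block_size * n_clusters)],
    cluster = rep(seq_len(n_clusters), each = block_size),
    shift = cluster_shift
  )
  purity <- setNames(runif(n_tumor, 0.4, 1.6), tumor_ids)

  ## target expression -------------------------------------------------------
  build_expr <- function(tf_mat, samp_ids, tumor) {
    n_s <- length(samp_ids)
    m <- matrix(rnorm(n_genes * n_s), n_genes,
                dimnames = list(genes, samp_ids))
    for (g in targets) {
      rows <- net[net$target == g, ]
      sig <- drop(
        crossprod(tf_mat[rows$tf, , drop = FALSE],
                  ifelse(rows$sign == "+", 1, -1) * rows$effect)
      )
      noise_sd <- sqrt(sum(rows$effect^2) / snr)
      m[g, ] <- sig + noise_sd * rnorm(n_s)
    }
    if (tumor) {
      for (g in cnv_effects$gene_id) {
        m[g, ] <- m[g, ] + dosage * cnv_mat[g, ]
      }
      for (i in seq_len(nrow(blocks))) {
        sel <- clusters == blocks$cluster[i]
        m[blocks$gene_id[i], sel] <- m[blocks$gene_id[i], sel] +
          blocks$shift[i] * purity[sel]
      }
    }
    m + baseline
  }
  expr_tumor <- build_expr(tf_tumor, tumor_ids, tumor = TRUE)
  expr_normal <- build_expr(tf_normal, normal_ids, tumor = FALSE)
  expr_mat <- rbind(
    cbind(expr_tumor, expr_normal),
    cbind(tf_tumor, tf_normal) + baseline
  )

  ## annotation and peaks ----------------------------------------------------
  all_features <- c(genes, tfs)
  annotation <- tibble(
    gene_id = all_features,
    chrom = paste0("chr", rep_len(1:5, length(all_features))),
    tss = 100000L * (seq_along(all_features) + 1L),
    strand = rep_len(c("+", "-"), length(all_features))
  )
  tss_of <- setNames(annotation$tss, annotation$gene_id)
  chrom_of <- setNames(annotation$chrom, annotation$gene_id)

  peak_ids <- sprintf("P%04d", seq_len(n_peaks))
  reg_peak <- setNames(peak_ids[seq_len(n_targets)], targets)
  reg_start <- tss_of[targets] + round(runif(n_targets, -15000, 14500))
  anchor <- sample(all_features, n_peaks - n_targets, replace = TRUE)
  near <- runif(n_peaks - n_targets) < 0.5
  decoy_start <- tss_of[anchor] +
    ifelse(near, round(runif(n_peaks - n_targets, -18000, 17500)),
           50000 + round(runif(n_peaks - n_targets, 0, 20000)))
  peaks_tbl <- tibble(
    peak_id = peak_ids,
    chrom = unname(c(chrom_of[targets], chrom_of[anchor])),
    start = unname(as.integer(c(reg_start, decoy_start))),
    end = unname(as.integer(c(reg_start, decoy_start)) + 500L)
  )

  # the regulatory peak's accessibility tracks its target's expression on
  # the ATAC samples (the correlation the best-peak selection exploits);
  # decoy peaks are independent noise
  sig_mat <- matrix(rnorm(n_peaks * n_atac), n_peaks,
                    dimnames = list(peak_ids, atac_ids)) + baseline
  for (g in targets) {
    rows <- net[net$target == g, ]
    sig_mat[reg_peak[[g]], ] <-
      expr_tumor[g, atac_ids] + rnorm(n_atac, sd = sqrt(sum(rows$effect^2) / snr))
  }
  peaks <- peak_set(peaks_tbl, as_feature_tibble(sig_mat, "peak_id"))

  ## motifs and peak sequences -----------------------------------------------
  repeat {
    consensus <- vapply(tfs, function(t_) {
      paste(sample(DNA_BASES, 8, replace = TRUE), collapse = "")
    }, character(1))
    if (!anyDuplicated(consensus)) break
  }
  pwms <- lapply(tfs, function(t_) {
    counts <- matrix(1, 4, 8, dimnames = list(DNA_BASES, NULL))
    idx <- match(strsplit(consensus[[t_]], "")[[1]], DNA_BASES)
    counts[cbind(idx, 1:8)] <- 18
    pwm(t_, counts)
  })
  names(pwms) <- tfs

  random_seq <- function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  }
  seqs <- vapply(peak_ids, function(p) random_seq(200), character(1))
  for (g in targets) {
    tf_set <- net$tf[net$target == g]
    s <- strsplit(seqs[[reg_peak[[g]]]], "")[[1]]
    at <- 20 + 12 * (seq_along(tf_set) - 1)  # non-overlapping slots
    for (i in seq_along(tf_set)) {
      s[at[i]:(at[i] + 7)] <- strsplit(consensus[[tf_set[i]]], "")[[1]]
    }
    seqs[[reg_peak[[g]]]] <- paste(s, collapse = "")
  }
  sequences <- tibble(peak_id = peak_ids, seq = unname(seqs))

  ## interaction scores: all planted pairs plus decoys -----------------------
  planted_pairs <- distinct(net, .data$tf, .data$target)
  n_decoy <- 2 * nrow(planted_pairs)
  decoy_pairs <- tibble(
    tf = sample(tfs, n_decoy, replace = TRUE),
    target = sample(genes, n_decoy, replace = TRUE)
  ) |>
    anti_join(planted_pairs, by = c("tf", "target")) |>
    distinct(.data$tf, .data$target)
  scores <- bind_rows(
    mutate(planted_pairs, score = round(runif(n(), 0.3, 1), 3)),
    mutate(decoy_pairs, score = round(runif(nrow(decoy_pairs), 0.1, 0.9), 3))
  )

  ## survival driven by a linear risk score ----------------------------------
  prognostic <- tibble(
    feature = c(planted_tfs[1], targets[1]),
    coef = c(1.0, -0.8)
  )
  lp <- drop(
    crossprod(expr_mat[prognostic$feature, tumor_ids, drop = FALSE] - baseline,
              prognostic$coef)
  )
  t_true <- rexp(n_tumor, rate = exp(lp) / 500)
  cens <- runif(n_tumor, 1, 1500)
  survival <- tibble(
    sample_id = tumor_ids,
    time = round(pmin(t_true, cens), 2) + 0.01,
    event = as.integer(t_true <= cens)
  )

  ## curated lists -----------------------------------------------------------
  classed <- sample(genes, min(60, n_genes))
  gene_lists <- list(
    ir_genes = genes,
    cycle_steps = tibble(gene_id = targets,
                         step = sample(1:7, n_targets, replace = TRUE)),
    classes = tibble(gene_id = classed,
                     class = sample(c("stimulatory", "inhibitory"),
                                    length(classed), replace = TRUE))
  )

  truth <- list(
    network = net,
    events = as_feature_tibble(events, "tf"),
    cluster_blocks = blocks,
    purity = tibble(sample_id = tumor_ids, purity = unname(purity)),
    regulatory_peaks = tibble(gene_id = targets,
                              peak_id = unname(reg_peak[targets])),
    cnv_effects = cnv_effects,
    prognostic_features = prognostic,
    consensus_motifs = tibble(tf = tfs, consensus = unname(consensus)),
    seed = seed
  )

  structure(
    list(
      expr = as_feature_tibble(expr_mat, "gene_id"),
      sample_info = sample_info,
      peaks = peaks,
      sequences = sequences,
      pwms = pwms,
      annotation = annotation,
      scores = scores,
      cnv = as_feature_tibble(cnv_mat, "gene_id"),
      survival = survival,
      gene_lists = gene_lists,
      truth = truth
    ),
    class = "immureg_cohort"
  )
}

#' @export
print.immureg_cohort <- function(x, ...) {
  cat(sprintf(
    "<immureg_cohort> %d features x %d samples, %d peaks, %d planted edges\n",
    nrow(x$expr), ncol(x$expr) - 1L, nrow(x$peaks$peaks), nrow(x$truth$network)
  ))
  invisible(x)
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' @param cohort An `immureg_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_expression(cohort$expr, fp("expression.tsv"))
  readr::write_tsv(cohort$sample_info, fp("samples.tsv"))
  p <- cohort$peaks$peaks
  np <- data.frame(p$chrom, p$start, p$end, p$peak_id, 0L, ".",
                   0, -1, -1, -1)
  readr::write_tsv(np, fp("peaks.narrowPeak"), col_names = FALSE)
  readr::write_tsv(cohort$peaks$signal, fp("atac_signal.tsv"))
  write_peak_sequences(cohort$sequences, fp("peaks.fa"))
  write_jaspar_pfm(cohort$pwms, fp("motifs.jaspar"))
  readr::write_tsv(cohort$annotation, fp("genes.tsv"))
  readr::write_tsv(cohort$scores, fp("interaction_scores.tsv"))
  readr::write_tsv(cohort$cnv, fp("cnv.tsv"))
  readr::write_tsv(cohort$survival, fp("clinical.tsv"))
  readr::write_tsv(tibble(gene_id = cohort$gene_lists$ir_genes),
                   fp("ir_genes.tsv"))
  readr::write_tsv(cohort$gene_lists$cycle_steps, fp("cycle_steps.tsv"))
  readr::write_tsv(cohort$gene_lists$classes, fp("classes.tsv"))
  invisible(dir)
}
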