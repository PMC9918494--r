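test_that("spearman correlation matches hand rank arithmetic", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_cor(1:4, c(40, 30, 20, 10))$rho, -1)
  # d = (-1, 1, -1, 1, 0), sum d^2 = 4, rho = 1 - 6*4/(5*24) = 0.8
  res <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 0.8)
  expect_equal(res$rho, unname(cor(1:5, c(2, 1, 4, 3, 5),
                                   method = "spearman")))
  con <- spearman_cor(rep(2, 5), 1:5)
  expect_equal(con$rho, 0)
  expect_equal(con$p_value, 1)
  expect_true(con$degenerate)
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(20)
  for (i in 1:5) {
    x <- rnorm(12)
    y <- rnorm(12)
    base <- spearman_cor(x, y)
    expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
    expect_equal(spearman_cor(x, 3 * y - 17)$rho, base$rho)
    expect_equal(spearman_cor(exp(x), y^3)$p_value, base$p_value)
  }
})

test_that("peak linking follows the +/-20 kb overlap convention", {
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 50000L)
  peaks <- tibble::tibble(
    peak_id = c("in_left", "out_left", "straddle", "wrong_chrom", "covers"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(30000L, 29000L, 29500L, 30000L, 49900L),
    end = c(30500L, 29900L, 30500L, 30500L, 50100L)
  )
  hit <- link_peaks_to_gene(gene, peaks)
  expect_setequal(hit$peak_id, c("in_left", "straddle", "covers"))
  expect_equal(hit$distance_to_tss[hit$peak_id == "in_left"], 19500L)
  expect_equal(hit$distance_to_tss[hit$peak_id == "covers"], 0L)
})

test_that("peak linking agrees with a brute-force interval scan", {
  set.seed(21)
  peaks <- tibble::tibble(
    peak_id = sprintf("p%03d", 1:300),
    chrom = sample(c("chr1", "chr2"), 300, TRUE),
    start = as.integer(sample.int(2e5, 300))
  )
  peaks$end <- peaks$start + as.integer(sample.int(2000, 300))
  for (i in 1:15) {
    gene <- tibble::tibble(gene_id = "g",
                           chrom = sample(c("chr1", "chr2"), 1),
                           tss = sample.int(2e5, 1))
    got <- sort(link_peaks_to_gene(gene, peaks, window = 20000)$peak_id)
    brute <- peaks$peak_id[vapply(seq_len(300), function(j) {
      peaks$chrom[j] == gene$chrom &&
        peaks$start[j] < gene$tss + 20000 && peaks$end[j] > gene$tss - 20000
    }, logical(1))]
    expect_equal(got, sort(brute))
  }
})

test_that("best-peak selection maximizes |rho| with documented tie-breaks", {
  set.seed(22)
  expr <- setNames(rnorm(20), sprintf("a%02d", 1:20))
  strong <- expr + rnorm(20, sd = 0.2)
  weak <- expr + rnorm(20, sd = 2)
  sig <- rbind(strong, weak, strong)
  rownames(sig) <- c("pA", "pB", "pC")
  ps <- peak_set(
    tibble::tibble(peak_id = c("pA", "pB", "pC"), chrom = "chr1",
                   start = c(100L, 300L, 500L), end = c(200L, 400L, 600L)),
    as_feature_tibble(sig, "peak_id")
  )
  cand <- tibble::tibble(peak_id = c("pA", "pB", "pC"),
                         distance_to_tss = c(500L, 100L, 500L))
  best <- select_best_peak(expr, ps, cand)
  # pA and pC have identical signal: tie on |rho| and distance -> peak id
  expect_equal(best$peak_id, "pA")
  expect_gt(abs(best$rho), 0.8)

  cand2 <- tibble::tibble(peak_id = c("pA", "pC"),
                          distance_to_tss = c(500L, 100L))
  expect_equal(select_best_peak(expr, ps, cand2)$peak_id, "pC")

  # a lone uncorrelated candidate fails the p threshold
  lone <- tibble::tibble(peak_id = "pB", distance_to_tss = 0L)
  sig2 <- rbind(pB = rnorm(20))
  colnames(sig2) <- names(expr)
  ps2 <- peak_set(
    tibble::tibble(peak_id = "pB", chrom = "chr1", start = 1L, end = 2L),
    as_feature_tibble(sig2, "peak_id")
  )
  expect_null(select_best_peak(expr, ps2, lone))
  expect_error(select_best_peak(setNames(rnorm(4), letters[1:4]), ps, cand),
               "matched")
})

test_that("planted regulatory peaks win the selection in simulation", {
  set.seed(23)
  wins <- 0L
  for (i in 1:40) {
    expr <- setNames(rnorm(20), sprintf("a%02d", 1:20))
    sig <- rbind(planted = expr + rnorm(20, sd = 0.3),
                 matrix(rnorm(5 * 20), 5,
                        dimnames = list(sprintf("decoy%d", 1:5), NULL)))
    ps <- peak_set(
      tibble::tibble(peak_id = rownames(sig), chrom = "chr1",
                     start = 100L * (1:6), end = 100L * (1:6) + 50L),
      as_feature_tibble(sig, "peak_id")
    )
    cand <- tibble::tibble(peak_id = rownames(sig),
                           distance_to_tss = 1000L)
    best <- select_best_peak(expr, ps, cand)
    if (!is.null(best) && best$peak_id == "planted") wins <- wins + 1L
  }
  expect_gte(wins, 38L)  # >= 95% recovery
})

test_that("motif scanning finds planted and reverse-complement sites", {
  counts <- matrix(1, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  motif <- c("A", "C", "G", "T", "T", "G", "C", "A")
  counts[cbind(match(motif, rownames(counts)), 1:8)] <- 18
  w <- pwm("TFX", counts)
  seq_fwd <- paste0(strrep("G", 10), "ACGTTGCA", strrep("C", 10))
  hits <- scan_motifs(w, seq_fwd)
  # palindrome-free check: one forward hit at offset 11
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$position, 11)

  rc <- paste0(strrep("G", 6), "TGCAACGT", strrep("G", 6))
  hits_rc <- scan_motifs(w, rc)
  expect_true(any(hits_rc$strand == "-" & hits_rc$position == 7))

  expect_equal(nrow(scan_motifs(w, "ACG")), 0)
  expect_error(scan_motifs(w, "ACGTXACGT"), "alphabet")
  # N scores as background: degrades but does not error
  withN <- scan_motifs(w, paste0(strrep("G", 10), "ACGNTGCA", strrep("C", 10)),
                       score_fraction = 0.5)
  expect_true(all(withN$score < max(hits$score)))
})

test_that("random-sequence hit counts match the enumerated distribution", {
  set.seed(24)
  counts <- matrix(1, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- sample(1:4, 10, TRUE)
  counts[cbind(idx, 1:10)] <- 18
  w <- pwm("TFY", counts)
  lo <- log2(sweep(counts + 0.5, 2, colSums(counts) + 2, "/") / 0.25)
  # exact per-position distribution of the score under iid uniform bases
  dist <- 0
  for (j in 1:10) dist <- as.vector(outer(dist, lo[, j], "+"))
  thr <- 0.85 * sum(apply(lo, 2, max))
  p_hit <- mean(dist >= thr)
  n_seq <- 120
  len <- 500
  observed <- sum(vapply(seq_len(n_seq), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    nrow(scan_motifs(w, s, score_fraction = 0.85))
  }, numeric(1)))
  expected <- 2 * (len - 10 + 1) * n_seq * p_hit
  expect_lt(abs(observed - expected), 4 * sqrt(expected + 1))
})

test_that("single-sample deviation calls behave at the reference and tails", {
  ref <- rnorm(100)
  at_mean <- single_sample_deviation(mean(ref), ref)
  expect_equal(at_mean$statistic, 0)
  expect_equal(at_mean$direction, "normal")

  far <- single_sample_deviation(mean(ref) + 10 * sd(ref), ref)
  expect_equal(far$direction, "high")
  expect_lt(far$p_value, 1e-10)

  const <- single_sample_deviation(2, rep(2, 10))
  expect_equal(const$direction, "normal")
  expect_true(const$degenerate)
  off_const <- single_sample_deviation(3, rep(2, 10))
  expect_equal(off_const$direction, "high")
  expect_equal(off_const$p_value, 0)
  expect_error(single_sample_deviation(1, c(1, 2)), ">= 3")
})

test_that("sign inference reproduces the full 27-combination truth table", {
  states <- c("high", "low", "normal")
  grid <- expand.grid(peak = states, tf = states, gene = states,
                      stringsAsFactors = FALSE)
  got <- infer_regulation_sign(grid$peak, grid$tf, grid$gene)
  expected <- ifelse(
    grid$peak == "high" & grid$tf == "high" & grid$gene == "high", "+",
    ifelse(grid$peak == "high" & grid$tf == "high" & grid$gene == "low", "-",
           NA_character_)
  )
  expect_identical(got, expected)
  # the two documented anchor cases
  expect_identical(infer_regulation_sign("high", "high", "high"), "+")
  expect_identical(infer_regulation_sign("high", "high", "low"), "-")
  # closed chromatin precludes any call
  expect_true(is.na(infer_regulation_sign("normal", "high", "high")))
})

test_that("a repressed gene yields exactly the planted edge, score-verified", {
  candidates <- tibble::tibble(
    gene_id = c("HSP90B1", "HSP90B1"),
    peak_id = "pk1",
    tf = c("JUN", "NOSCORE")
  )
  gene_calls <- tibble::tibble(id = "HSP90B1", direction = "low",
                               p_value = 2e-5)
  tf_calls <- tibble::tibble(id = c("JUN", "NOSCORE"), direction = "high",
                             p_value = c(1e-4, 1e-4))
  peak_calls <- tibble::tibble(id = "pk1", direction = "high")
  scores <- tibble::tibble(tf = "JUN", target = "HSP90B1", score = 0.474)
  validation <- list(jaspar = tibble::tibble(tf = "JUN", target = "HSP90B1"))
  edges <- build_sample_network("TCGA-86-A4P8-01", candidates, gene_calls,
                                tf_calls, peak_calls, scores, validation)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$tf, "JUN")
  expect_equal(edges$sign, "-")
  expect_equal(edges$weight, 0.474)
  expect_equal(edges$evidence, "jaspar")

  # with a normal peak nothing is emitted
  edges2 <- build_sample_network(
    "s", candidates, gene_calls, tf_calls,
    tibble::tibble(id = "pk1", direction = "normal"), scores
  )
  expect_equal(nrow(edges2), 0)
})

test_that("the cohort pipeline emits only planted regulations", {
  co <- test_cohort()
  res <- single_sample_networks(
    expr = co$expr, sample_info = co$sample_info, peaks = co$peaks,
    annotation = co$annotation, ir_genes = co$gene_lists$ir_genes,
    scores = co$scores, pwms = co$pwms, sequences = co$sequences
  )
  expect_gt(nrow(res$edges), 5)
  truth_keys <- paste(co$truth$network$tf, co$truth$network$target,
                      co$truth$network$sign)
  edge_keys <- paste(res$edges$tf, res$edges$target, res$edges$sign)
  expect_gte(mean(edge_keys %in% truth_keys), 0.9)
  # the selected peak is overwhelmingly the planted one
  rp <- co$truth$regulatory_peaks
  lk <- dplyr::inner_join(res$links, rp, by = "gene_id",
                          suffix = c("", ".true"))
  expect_gte(mean(lk$peak_id == lk$peak_id.true), 0.9)
})
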