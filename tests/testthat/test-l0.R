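test_that("gamma = 0 reduces to OLS and huge gamma to the zero model", {
  set.seed(30)
  X <- scale(matrix(rnorm(50 * 6), 50))
  y <- drop(X %*% c(1, -2, 0, 0, 0.5, 0)) + rnorm(50)
  y <- y - mean(y)
  ols <- qr.coef(qr(X), y)
  fit0 <- l0_fit(y, X, gamma = 0)
  expect_equal(fit0$beta, unname(ols), tolerance = 1e-8)
  fit_inf <- l0_fit(y, X, gamma = 1e9)
  expect_equal(fit_inf$beta, rep(0, 6))
  expect_equal(fit_inf$objective, 0.5 * sum(y^2))
  expect_error(l0_fit(y, X, gamma = -1), "gamma")
  expect_error(l0_fit(y, X * 10, gamma = 1), "standardized")
})

test_that("orthogonal designs match the hard-threshold closed form", {
  set.seed(31)
  for (i in 1:10) {
    n <- 48
    p <- 6
    Q <- qr.Q(qr(matrix(rnorm(n * p), n)))
    X <- sqrt(n) * Q  # X'X = n I
    beta_true <- c(2, -1, 0.6, 0, 0, 0)
    y <- drop(X %*% beta_true) + rnorm(n)
    y <- y - mean(y)
    gamma <- exp(runif(1, log(1), log(100)))
    z <- drop(crossprod(X, y)) / n
    expected <- ifelse(z^2 * n > 2 * gamma, z, 0)
    fit <- l0_fit(y, X, gamma)
    expect_equal(fit$beta, expected, tolerance = 1e-8)
  }
})

test_that("the solver equals exhaustive best-subset enumeration at p = 8", {
  for (i in 1:20) {
    inst <- random_instance(n = 40, p = 8, seed = 300 + i)
    fit <- l0_fit(inst$y, inst$X, inst$gamma)
    oracle <- enumerate_l0(inst$y, inst$X, inst$gamma)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-8)
  }
})

test_that("the objective is monotone and never worse than the zero model", {
  for (i in 1:10) {
    inst <- random_instance(n = 35, p = 10, seed = 500 + i)
    fit <- l0_fit(inst$y, inst$X, inst$gamma)
    expect_true(all(diff(fit$trace) <= 1e-9))
    expect_lte(fit$objective, 0.5 * sum(inst$y^2) + 1e-12)
  }
})

test_that("noiseless single-regulator signal is recovered exactly", {
  set.seed(32)
  X <- scale(matrix(rnorm(60 * 20), 60))
  colnames(X) <- sprintf("TF%02d", 1:20)
  y <- drop(2 * X[, 3])
  fit <- suppressWarnings(l0_path_select(y, X, seed = 1))
  expect_equal(fit$support, "TF03")
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
})

test_that("pure noise responses select nothing or explain nothing", {
  set.seed(33)
  clean <- 0L
  for (i in 1:30) {
    X <- matrix(rnorm(100 * 20), 100)
    colnames(X) <- sprintf("TF%02d", 1:20)
    y <- rnorm(100)
    fit <- l0_path_select(y, X, seed = i)
    if (length(fit$support) == 0 || fit$r_squared < 0.2) clean <- clean + 1L
  }
  expect_gte(clean, 27L)  # ~ 90% of seeds
})

test_that("a planted 3-TF model is recovered at high rate", {
  set.seed(34)
  exact <- 0L
  covered <- 0L
  sizes <- integer(0)
  n_sim <- 40
  truth <- c("TF04", "TF17", "TF32")
  for (i in seq_len(n_sim)) {
    X <- matrix(rnorm(100 * 50), 100)
    colnames(X) <- sprintf("TF%02d", 1:50)
    beta <- numeric(50)
    beta[c(4, 17, 32)] <- c(1, -1, 0.8)
    signal <- drop(X %*% beta)
    y <- signal + rnorm(100, sd = sd(signal) / sqrt(10))  # SNR 10
    fit <- l0_path_select(y, X, seed = i)
    if (all(truth %in% fit$support)) covered <- covered + 1L
    if (setequal(fit$support, truth)) exact <- exact + 1L
    sizes <- c(sizes, length(fit$support))
  }
  # every planted TF is found essentially always; CV-minimum penalty choice
  # admits an occasional spurious extra, so exact-support recovery is lower
  expect_gte(covered / n_sim, 0.95)
  expect_gte(exact / n_sim, 0.65)
  expect_equal(median(sizes), 3)
})

test_that("refit R^2 is monotone along decreasing gamma on orthogonal designs", {
  set.seed(35)
  n <- 64
  X <- sqrt(n) * qr.Q(qr(matrix(rnorm(n * 8), n)))
  y <- drop(X %*% c(1.5, -1, 0.7, 0.4, 0, 0, 0, 0)) + rnorm(n)
  y <- y - mean(y)
  grid <- exp(seq(log(200), log(0.01), length.out = 25))
  r2 <- vapply(grid, function(g) {
    b <- l0_fit(y, X, g)$beta
    s <- which(b != 0)
    if (length(s) == 0) return(0)
    1 - sum(lm.fit(X[, s, drop = FALSE], y)$residuals^2) / sum(y^2)
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("cluster networks reduce to simple regression for one TF", {
  set.seed(36)
  n <- 60
  tf <- rnorm(n)
  target <- -1.3 * tf + rnorm(n, sd = 0.4)
  expr <- toy_expr(rbind(tf, target), genes = c("TF01", "G1"),
                   samples = sprintf("s%02d", 1:n))
  info <- tibble::tibble(sample_id = sprintf("s%02d", 1:n), cohort = "tumor",
                         cluster = 1L)
  net <- infer_cluster_network(expr, info,
                               tibble::tibble(target = "G1", tf = "TF01"),
                               seed = 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sign, "-")
  expect_equal(sign(cov(tf, target)), -1)
  expect_gt(net$fits$r_squared, 0.8)
})

test_that("identical clusters give identical networks", {
  set.seed(37)
  n <- 40
  tfs <- matrix(rnorm(3 * n), 3, dimnames = list(sprintf("TF%02d", 1:3), NULL))
  g1 <- drop(crossprod(tfs, c(1, 0, -0.8))) + rnorm(n, sd = 0.3)
  block <- rbind(tfs, G1 = g1)
  expr <- toy_expr(cbind(block, block),
                   genes = rownames(block),
                   samples = sprintf("s%02d", 1:(2 * n)))
  info <- tibble::tibble(sample_id = sprintf("s%02d", 1:(2 * n)),
                         cohort = "tumor",
                         cluster = rep(1:2, each = n))
  pool <- tibble::tibble(target = "G1", tf = sprintf("TF%02d", 1:3))
  net <- infer_cluster_network(expr, info, pool, seed = 5)
  e1 <- dplyr::filter(net$edges, scope == "cluster_1")
  e2 <- dplyr::filter(net$edges, scope == "cluster_2")
  expect_equal(dplyr::select(e1, -scope), dplyr::select(e2, -scope))
})

test_that("zero-variance targets are skipped with a warning", {
  expr <- toy_expr(rbind(TF01 = rnorm(10), G1 = rep(2, 10)),
                   genes = c("TF01", "G1"), samples = sprintf("s%d", 1:10))
  info <- tibble::tibble(sample_id = sprintf("s%d", 1:10), cohort = "tumor",
                         cluster = 1L)
  expect_warning(
    net <- infer_cluster_network(expr, info,
                                 tibble::tibble(target = "G1", tf = "TF01")),
    "zero variance"
  )
  expect_equal(nrow(net$edges), 0)
})

test_that("CNV correlation recovers rank identity, nulls and dosage", {
  set.seed(38)
  n <- 200
  samples <- sprintf("s%03d", 1:n)
  info <- tibble::tibble(sample_id = samples, cohort = "tumor", cluster = 1L)
  cnv_vals <- rnorm(n)
  # expression equal to the CNV ranks: rho = 1 exactly
  expr1 <- toy_expr(rbind(g1 = rank(cnv_vals)), genes = "g1",
                    samples = samples)
  cnv1 <- toy_expr(rbind(g1 = cnv_vals), genes = "g1", samples = samples)
  cc <- cnv_expression_correlation(expr1, cnv1, info)
  expect_equal(cc$rho, 1)

  # independent CNV: small |rho|
  rhos <- vapply(1:30, function(i) {
    e <- toy_expr(rbind(g1 = rnorm(n)), genes = "g1", samples = samples)
    cnv_expression_correlation(e, cnv1, info)$rho
  }, numeric(1))
  expect_gte(mean(abs(rhos) < 0.2), 0.95)

  # planted dosage effect in the cohort generator's regime
  dose <- toy_expr(rbind(g1 = 0.5 * cnv_vals + rnorm(n)), genes = "g1",
                   samples = samples)
  cc2 <- cnv_expression_correlation(dose, cnv1, info)
  expect_gt(cc2$rho, 0.3)

  # too few shared samples -> skipped with a warning
  info_small <- info[1:3, ]
  expect_warning(
    out <- cnv_expression_correlation(expr1, cnv1, info_small),
    "skipped"
  )
  expect_equal(nrow(out), 0)
})

test_that("tidiers expose estimates and fit summaries", {
  set.seed(39)
  X <- matrix(rnorm(60 * 10), 60)
  colnames(X) <- sprintf("TF%02d", 1:10)
  y <- drop(1.5 * X[, 2]) + rnorm(60, sd = 0.3)
  fit <- l0_path_select(y, X, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  expect_true("TF02" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$nobs, 60)
  expect_gt(gl$r.squared, 0.8)
})
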