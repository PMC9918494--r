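# Population-level network inference: per-target best-subset (L0) regression
# with cross-validated penalty choice, OLS refit statistics, the R^2 "TF
# regulatory value", and per-cluster CNV/expression Spearman correlation.
# The solver itself (coordinate descent + local swap search) lives in
# src/l0cd.cpp.

check_standardized <- function(X) {
  scale2 <- colSums(X^2) / nrow(X)
  if (any(scale2 < 0.64 | scale2 > 1.44)) {
    stop_usage("columns of X must be standardized to ~unit variance")
  }
  invisible(X)
}

#' L0-penalized least squares for one penalty value
#'
#' Minimizes `0.5 * ||y - X beta||^2 + gamma * ||beta||_0` by cyclic
#' coordinate descent with hard-thresholding updates followed by local
#' combinatorial search (single support swaps, best improvement first, with
#' coordinate-descent polish after every accepted move). Run from two warm
#' starts (the zero vector and the hard-thresholded univariate solution);
#' the better fixed point is returned. The objective is non-increasing at
#' every accepted move.
#'
#' @param y Centered response vector (length >= 3).
#' @param X Matrix with columns standardized to (approximately) unit
#'   variance.
#' @param gamma Non-negative L0 penalty weight.
#' @param max_sweeps,tol Coordinate-descent stopping controls.
#' @param swap_rounds Maximum local-search rounds.
#' @param beta0 Optional warm-start coefficient vector.
#' @param dense_start Also start from the full OLS solution (lets the local
#'   search prune into supports that coordinate-wise additions cannot
#'   reach). On by default; path fitting disables it and relies on warm
#'   starts instead.
#' @param search Run the local combinatorial search after coordinate
#'   descent. Cross-validation paths turn it off for speed and refit the
#'   support by OLS before predicting.
#' @return List of class `l0_raw`: `beta`, `objective`, `trace` (objective
#'   after each sweep/move of the winning start).
#' @export
l0_fit <- function(y, X, gamma, max_sweeps = 200, tol = 1e-10,
                   swap_rounds = 100, beta0 = NULL, dense_start = TRUE,
                   search = TRUE) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop_usage("length(y) must equal nrow(X)")
  if (nrow(X) < 3) stop_usage("need n >= 3 observations")
  if (!is.finite(gamma) || gamma < 0) stop_usage("gamma must be >= 0")
  check_standardized(X)
  s <- colSums(X^2)
  z <- drop(crossprod(X, y)) / pmax(s, .Machine$double.eps)
  starts <- list(numeric(ncol(X)), ifelse(z^2 * s > 2 * gamma, z, 0))
  if (dense_start && ncol(X) < nrow(X)) {
    # dense start: local search can prune a full OLS solution down to
    # supports that single-coordinate additions never reach
    ols <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (!is.null(ols) && all(is.finite(ols))) {
      starts <- c(starts, list(unname(ols)))
    }
  }
  if (!is.null(beta0)) starts <- c(starts, list(beta0))
  fits <- lapply(starts, function(b0) {
    .l0_cd_swap(X, y, gamma, b0, max_sweeps, tol, swap_rounds, search)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  structure(
    list(beta = drop(best$beta), objective = best$objective,
         trace = best$trace),
    class = "l0_raw"
  )
}

l0_gamma_grid <- function(X, y, n_gamma = 50, span = 1e-4) {
  s <- colSums(X^2)
  z <- drop(crossprod(X, y)) / pmax(s, .Machine$double.eps)
  gmax <- max(z^2 * s / 2)
  if (!is.finite(gmax) || gmax <= 0) gmax <- 1
  exp(seq(log(gmax * 1.01), log(gmax * span), length.out = n_gamma))
}

fit_l0_path <- function(X, y, gamma_grid, search = TRUE, ...) {
  beta <- numeric(ncol(X))
  lapply(gamma_grid, function(g) {
    fit <- l0_fit(y, X, g, beta0 = beta, dense_start = FALSE,
                  search = search, ...)
    beta <<- fit$beta
    fit$beta
  })
}

# OLS refit of y on the support of beta; returns the refit coefficient
# vector on the full coordinate system (zeros off-support).
refit_support <- function(X, y, beta) {
  s <- which(beta != 0)
  out <- numeric(length(beta))
  if (length(s) == 0) return(out)
  cf <- qr.coef(qr(X[, s, drop = FALSE]), y)
  cf[!is.finite(cf)] <- 0
  out[s] <- cf
  out
}

#' Best-subset regression with cross-validated penalty selection
#'
#' Fits the L0 path over a descending penalty grid with warm starts, picks
#' the penalty minimizing mean K-fold out-of-fold squared error (ties go to
#' the sparser model), then refits OLS on the selected support: the refit
#' `R^2` on the full data (clamped to \[0, 1\]) is the TF regulatory value,
#' and two-sided t-tests on the refit coefficients give per-TF p-values
#' (post-selection, hence anti-conservative; see the methods vignette).
#'
#' @param y Response vector; centered internally.
#' @param X Predictor matrix; columns z-scored internally (zero-variance
#'   columns are excluded).
#' @param gamma_grid Descending penalty grid; derived from the data when
#'   NULL.
#' @param k_folds Number of CV folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @param n_gamma Grid size when `gamma_grid` is NULL.
#' @return Object of class `l0_fit`: `support`, `beta` (refit OLS, on the
#'   standardized predictor scale), `gamma`, `r_squared`, `tf_p_values`,
#'   `cv` (tibble `gamma`, `cv_error`), `n`, `seed`.
#' @export
l0_path_select <- function(y, X, gamma_grid = NULL, k_folds = 5, seed = 1,
                           n_gamma = 50) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_folds < 2) stop_usage("need k_folds >= 2")
  if (length(y) != n) stop_usage("length(y) must equal nrow(X)")
  keep <- which(apply(X, 2, sd) > 0)
  if (length(keep) == 0) stop_usage("all predictors have zero variance")
  Xs <- scale(X[, keep, drop = FALSE])
  yc <- y - mean(y)
  if (is.null(gamma_grid)) {
    gamma_grid <- l0_gamma_grid(Xs, yc, n_gamma)
  }
  if (length(gamma_grid) == 0) stop_usage("empty gamma grid")
  if (is.unsorted(rev(gamma_grid))) stop_usage("gamma_grid must be descending")

  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  err <- matrix(NA_real_, length(gamma_grid), k_folds)
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    # re-standardize on the training part of the fold so the solver's
    # unit-variance contract holds within the fold
    ctr <- colMeans(Xs[tr, , drop = FALSE])
    scl <- apply(Xs[tr, , drop = FALSE], 2, sd)
    ok <- scl > 0
    Xtr <- sweep(sweep(Xs[tr, ok, drop = FALSE], 2, ctr[ok]), 2,
                 scl[ok], "/")
    Xte <- sweep(sweep(Xs[!tr, ok, drop = FALSE], 2, ctr[ok]), 2,
                 scl[ok], "/")
    ytr_mean <- mean(yc[tr])
    ytr <- yc[tr] - ytr_mean
    path <- fit_l0_path(Xtr, ytr, gamma_grid, search = FALSE)
    for (gi in seq_along(gamma_grid)) {
      refit <- refit_support(Xtr, ytr, path[[gi]])
      pred <- ytr_mean + drop(Xte %*% refit)
      err[gi, k] <- mean((yc[!tr] - pred)^2)
    }
  }
  cv_err <- rowMeans(err)
  best_gi <- which(cv_err <= min(cv_err) + 1e-12)[1]  # ties -> sparser model
  gamma <- gamma_grid[best_gi]

  path <- fit_l0_path(Xs, yc, gamma_grid)
  beta_cd <- path[[best_gi]]
  support <- which(beta_cd != 0)
  if (length(support) >= n) {
    warn("selected support >= n; truncating by largest |beta|")
    support <- support[order(-abs(beta_cd[support]))][seq_len(n - 1)]
  }

  tss <- sum(yc^2)
  if (length(support) == 0) {
    r2 <- 0
    beta <- numeric(0)
    pvals <- numeric(0)
  } else {
    df <- data.frame(y = yc, Xs[, support, drop = FALSE])
    names(df) <- c("y", colnames(Xs)[support])
    fit <- lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    beta <- coef(fit)[-1]
    pvals <- sm[-1, 4]
    names(beta) <- names(pvals) <- colnames(Xs)[support]
    r2 <- max(0, min(1, 1 - sum(fit$residuals^2) / tss))
  }
  structure(
    list(
      support = colnames(Xs)[support] %||% support,
      beta = beta, gamma = gamma, r_squared = r2, tf_p_values = pvals,
      cv = tibble(gamma = gamma_grid, cv_error = cv_err),
      n = n, seed = seed
    ),
    class = "l0_fit"
  )
}

#' @export
print.l0_fit <- function(x, ...) {
  cat(sprintf("<l0_fit> %d predictors selected, R^2 = %.3f, gamma = %.3g\n",
              length(x$support), x$r_squared, x$gamma))
  invisible(x)
}

#' Per-cluster regulatory network by best-subset regression
#'
#' For every (target, cluster) pair regresses the target's expression on its
#' candidate TF pool within the cluster's samples via [l0_path_select()].
#' Edge sign and weight come from the refit OLS coefficient, the edge
#' p-value from its t-test; the per-target refit `R^2` is reported as the
#' TF regulatory value.
#'
#' @param expr Wide expression tibble covering targets and TFs.
#' @param sample_info Tibble `sample_id`, `cohort`, `cluster`.
#' @param tf_pool Tibble `target`, `tf`: the candidate regulators per
#'   target (e.g. from the single-sample framework).
#' @param gamma_grid Optional penalty grid passed through.
#' @param k_folds CV folds.
#' @param seed Base seed; each target uses `seed + target index - 1`, so
#'   identical inputs give identical networks.
#' @return List with `edges` (scope `cluster_<k>`), `fits` (tibble `target`,
#'   `cluster`, `r_squared`, `gamma`, `n_selected`), `models` (nested list
#'   of [l0_path_select()] objects).
#' @export
infer_cluster_network <- function(expr, sample_info, tf_pool,
                                  gamma_grid = NULL, k_folds = 5, seed = 1) {
  m <- as_feature_matrix(expr)
  targets <- intersect(unique(tf_pool$target), rownames(m))
  clusters <- sort(unique(sample_info$cluster[!is.na(sample_info$cluster)]))
  if (length(clusters) == 0) stop_usage("no cluster labels in sample_info")
  edges <- list()
  fits <- list()
  models <- list()
  for (cl in clusters) {
    samp <- intersect(
      sample_info$sample_id[!is.na(sample_info$cluster) &
                              sample_info$cluster == cl],
      colnames(m)
    )
    scope <- paste0("cluster_", cl)
    models[[scope]] <- list()
    for (g in targets) {
      tfs <- intersect(tf_pool$tf[tf_pool$target == g], rownames(m))
      tfs <- setdiff(tfs, g)
      if (length(tfs) == 0) next
      y <- m[g, samp]
      if (sd(y) == 0) {
        warn(sprintf("target %s has zero variance in cluster %s; skipped",
                     g, cl))
        next
      }
      fit <- l0_path_select(y, t(m[tfs, samp, drop = FALSE]),
                            gamma_grid = gamma_grid, k_folds = k_folds,
                            seed = seed + match(g, targets) - 1)
      models[[scope]][[g]] <- fit
      fits[[length(fits) + 1]] <- tibble(
        target = g, cluster = as.integer(cl), r_squared = fit$r_squared,
        gamma = fit$gamma, n_selected = length(fit$support)
      )
      if (length(fit$beta) > 0) {
        edges[[length(edges) + 1]] <- tibble(
          scope = scope, tf = names(fit$beta), target = g,
          sign = unname(ifelse(fit$beta > 0, "+", "-")),
          weight = unname(abs(fit$beta)),
          p_value = unname(fit$tf_p_values[names(fit$beta)]),
          evidence = ""
        )
      }
    }
  }
  list(
    edges = if (length(edges)) bind_rows(edges) else empty_edges(),
    fits = if (length(fits)) bind_rows(fits) else tibble(),
    models = models
  )
}

#' Per-cluster Spearman correlation between expression and copy number
#'
#' @param expr Wide expression tibble.
#' @param cnv Wide gene-level copy-number tibble.
#' @param sample_info Tibble `sample_id`, `cohort`, `cluster`.
#' @param min_n Minimum shared samples per (gene, cluster) (default 4).
#' @return Tibble `gene_id`, `cluster`, `rho`, `p_value`, `n`.
#' @export
cnv_expression_correlation <- function(expr, cnv, sample_info, min_n = 4) {
  me <- as_feature_matrix(expr)
  mc <- as_feature_matrix(cnv)
  genes <- intersect(rownames(me), rownames(mc))
  clusters <- sort(unique(sample_info$cluster[!is.na(sample_info$cluster)]))
  skipped <- 0L
  out <- purrr::map_dfr(clusters, function(cl) {
    samp <- intersect(
      sample_info$sample_id[!is.na(sample_info$cluster) &
                              sample_info$cluster == cl],
      intersect(colnames(me), colnames(mc))
    )
    if (length(samp) < min_n) {
      skipped <<- skipped + length(genes)
      return(NULL)
    }
    purrr::map_dfr(genes, function(g) {
      res <- spearman_cor(me[g, samp], mc[g, samp])
      tibble(gene_id = g, cluster = as.integer(cl), rho = res$rho,
             p_value = res$p_value, n = res$n)
    })
  })
  if (skipped > 0) {
    warn(sprintf("%d (gene, cluster) entries skipped for n < %d",
                 skipped, min_n))
  }
  out
}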