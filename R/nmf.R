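# Immune-subtype discovery: non-negative matrix factorization (Lee-Seung
# multiplicative updates, Frobenius objective), consensus clustering over
# repeated seeded runs, and cophenetic-coefficient rank selection.

shift_nonneg <- function(X) {
  mn <- min(X)
  if (mn < 0) X - mn else X
}

#' Non-negative matrix factorization
#'
#' Factorizes a non-negative matrix `X ~ W H` by multiplicative updates on
#' the Frobenius objective; the objective is non-increasing across
#' iterations. Matrices containing negative values (e.g. quantile-normalized
#' expression) are shifted by their global minimum first.
#'
#' @param X Numeric matrix (features x samples) or wide feature tibble.
#' @param rank Factorization rank, `2 <= rank < min(dim(X))` (rank 1 allowed
#'   for degenerate checks).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of update iterations.
#' @param tol Stop when the relative change of reconstruction error falls
#'   below this.
#' @return List of class `nmf_result`: `W`, `H`, `rank`,
#'   `reconstruction_error`, `seed`, and the per-iteration `trace`.
#' @export
nmf_factorize <- function(X, rank, seed = 1, max_iter = 500, tol = 1e-5) {
  if (is.data.frame(X)) X <- as_feature_matrix(X)
  X <- shift_nonneg(X)
  if (all(X == 0)) stop_usage("cannot factorize an all-zero matrix")
  if (rank >= min(dim(X))) stop_usage("rank must be < min(dim(X))")
  if (rank < 1) stop_usage("rank must be >= 1")
  set.seed(seed)
  eps <- .Machine$double.eps
  scale0 <- sqrt(mean(X) / rank)
  W <- matrix(runif(nrow(X) * rank, min = eps, max = scale0), nrow(X))
  H <- matrix(runif(rank * ncol(X), min = eps, max = scale0), rank)
  err <- norm(X - W %*% H, "F")
  trace <- err
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_err <- norm(X - W %*% H, "F")
    trace <- c(trace, new_err)
    if (abs(err - new_err) < tol * max(err, eps)) {
      err <- new_err
      break
    }
    err <- new_err
  }
  structure(
    list(W = W, H = H, rank = rank, reconstruction_error = err,
         seed = seed, trace = trace),
    class = "nmf_result"
  )
}

#' Consensus clustering over repeated NMF runs
#'
#' Runs `n_runs` seeded factorizations; per run each sample is assigned to
#' the argmax row of `H`. The consensus matrix holds co-clustering
#' frequencies; final labels come from average-linkage hierarchical
#' clustering of `1 - consensus` cut at `rank` clusters, and the cophenetic
#' coefficient is the Pearson correlation between the `1 - consensus`
#' distances and the cophenetic distances of that dendrogram.
#'
#' @inheritParams nmf_factorize
#' @param n_runs Number of factorization runs (>= 2).
#' @param base_seed Per-run seeds are `base_seed + run - 1`.
#' @return List of class `consensus_result`: `consensus` (samples x samples),
#'   `cophenetic`, `silhouette`, `labels` (tibble `sample_id`, `cluster`),
#'   `rank`.
#' @export
consensus_cluster <- function(X, rank, n_runs = 30, base_seed = 1,
                              max_iter = 500, tol = 1e-5) {
  if (is.data.frame(X)) X <- as_feature_matrix(X)
  if (n_runs < 2) stop_usage("need n_runs >= 2")
  n <- ncol(X)
  ids <- colnames(X) %||% as.character(seq_len(n))
  co <- matrix(0, n, n)
  for (run in seq_len(n_runs)) {
    fit <- nmf_factorize(X, rank, seed = base_seed + run - 1,
                         max_iter = max_iter, tol = tol)
    lab <- max.col(t(fit$H), ties.method = "first")
    if (length(unique(lab)) < rank) {
      inform(sprintf("run %d produced %d non-empty clusters (rank %d)",
                     run, length(unique(lab)), rank))
    }
    co <- co + outer(lab, lab, "==")
  }
  consensus <- co / n_runs
  dimnames(consensus) <- list(ids, ids)
  d <- as.dist(1 - consensus)
  hc <- hclust(d, method = "average")
  labels <- cutree(hc, k = rank)
  coph_d <- cophenetic(hc)
  coph <- if (sd(d) == 0 || sd(coph_d) == 0) 1 else cor(d, coph_d)
  sil <- if (length(unique(labels)) < 2) {
    NA_real_
  } else {
    mean(cluster::silhouette(labels, d)[, 3])
  }
  structure(
    list(consensus = consensus, cophenetic = coph, silhouette = sil,
         labels = tibble(sample_id = ids, cluster = unname(labels)),
         rank = rank),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> rank %d, cophenetic %.3f, silhouette %.3f\n",
              x$rank, x$cophenetic, x$silhouette))
  invisible(x)
}

#' Pick the factorization rank from a cophenetic profile
#'
#' The optimal rank is where the cophenetic coefficient stops rising and
#' starts its decline, i.e. the profile's peak; exact ties go to the larger
#' rank (a dip followed by full recovery is not a decline). If the peak sits
#' at the largest candidate rank no decline was observed and the choice is
#' returned with a warning. When every post-peak value stays within `delta`
#' of the peak the decline is reported as shallow.
#'
#' @param ranks Ascending integer ranks.
#' @param cophenetic Cophenetic coefficient per rank.
#' @param delta Tolerance used to flag a shallow (sub-`delta`) decline.
#' @return The selected rank.
#' @export
select_rank_from_profile <- function(ranks, cophenetic, delta = 0.005) {
  stopifnot(length(ranks) == length(cophenetic), length(ranks) >= 2)
  k <- length(ranks)
  peak <- max(cophenetic)
  best_i <- max(which(cophenetic >= peak - 1e-9))
  if (best_i == k) {
    warn("cophenetic never starts decreasing; selecting the largest rank")
    return(ranks[k])
  }
  if (max(cophenetic[(best_i + 1):k]) > peak - delta) {
    inform(sprintf(
      "cophenetic decline after rank %d is shallower than delta = %g",
      ranks[best_i], delta
    ))
  }
  ranks[best_i]
}

#' Rank selection by consensus NMF over a rank range
#'
#' @inheritParams consensus_cluster
#' @param ranks Contiguous ascending ranks to evaluate (default 2:6).
#' @param delta Decline tolerance for [select_rank_from_profile()].
#' @return List of class `rank_selection`: `best_rank`, `profile` (tibble
#'   `rank`, `cophenetic`, `silhouette`), and the per-rank
#'   [consensus_cluster()] `results`.
#' @export
select_rank <- function(X, ranks = 2:6, n_runs = 30, base_seed = 1,
                        delta = 0.005, max_iter = 500, tol = 1e-5) {
  if (length(ranks) < 2) stop_usage("need at least 2 candidate ranks")
  if (any(diff(ranks) != 1)) stop_usage("ranks must be contiguous ascending")
  results <- lapply(ranks, function(r) {
    consensus_cluster(X, r, n_runs = n_runs, base_seed = base_seed,
                      max_iter = max_iter, tol = tol)
  })
  profile <- tibble(
    rank = ranks,
    cophenetic = vapply(results, function(x) x$cophenetic, numeric(1)),
    silhouette = vapply(results, function(x) x$silhouette, numeric(1))
  )
  best <- select_rank_from_profile(ranks, profile$cophenetic, delta)
  structure(
    list(best_rank = best, profile = profile,
         results = setNames(results, paste0("rank_", ranks))),
    class = "rank_selection"
  )
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf("<rank_selection> best rank %d\n", x$best_rank))
  print(x$profile)
  invisible(x)
}
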