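# Shared fixtures built in code. The default cohort is generated once per
# test session and reused read-only.

.fixture_env <- new.env(parent = emptyenv())

test_cohort <- function(seed = 7) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_cohort(seed = seed)
  }
  .fixture_env[[key]]
}

# Tiny wide expression table: values is a genes x samples matrix.
toy_expr <- function(values, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  as_feature_tibble(values, "gene_id")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Exhaustive best-subset oracle: minimal 0.5*RSS + gamma*k over all supports.
enumerate_l0 <- function(y, X, gamma) {
  p <- ncol(X)
  best <- list(objective = 0.5 * sum(y^2), support = integer(0))
  for (k in seq_len(p)) {
    for (sub in utils::combn(p, k, simplify = FALSE)) {
      rss <- sum(lm.fit(X[, sub, drop = FALSE], y)$residuals^2)
      obj <- 0.5 * rss + gamma * k
      if (obj < best$objective - 1e-12) {
        best <- list(objective = obj, support = sub)
      }
    }
  }
  best
}

# Standardized random regression instance.
random_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  k <- sample(0:min(3, p), 1)
  beta <- numeric(p)
  if (k > 0) beta[sample(p, k)] <- runif(k, 0.5, 2) * sample(c(-1, 1), k, TRUE)
  y <- drop(X %*% beta) + rnorm(n)
  y <- y - mean(y)
  gamma <- exp(runif(1, log(0.1), log(2 * n)))
  list(X = X, y = y, gamma = gamma)
}
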