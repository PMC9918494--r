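# Prognostic risk scoring: L1-penalized Cox feature selection on a 7:3
# train/validation split with 10-fold CV (glmnet), the linear Risk Score,
# median stratification, Kaplan-Meier / log-rank evaluation and IPCW
# cumulative/dynamic time-dependent AUC.

#' Fit an L1-penalized Cox risk model
#'
#' Splits samples into training and validation sets, z-scores the features
#' on the training set, fits the Lasso-Cox path (Breslow ties) and picks the
#' penalty by k-fold cross-validated partial-likelihood deviance. Features
#' with non-zero coefficients form the risk model; coefficients are reported
#' on both the input expression scale (`zeta`, the Risk Score weights) and
#' the standardized scale (`zeta_std`).
#'
#' @param expr Wide expression tibble (`gene_id` + sample columns).
#' @param survival Survival tibble `sample_id`, `time`, `event`.
#' @param features Candidate features (row ids of `expr`); defaults to all.
#' @param k_folds CV folds (default 10).
#' @param train_fraction Fraction of samples in the training split
#'   (default 0.7).
#' @param seed Seed for the split and fold assignment.
#' @param lambda_grid Optional penalty grid; a single value skips CV.
#' @return Object of class `risk_model`: `features`, `zeta`, `zeta_std`,
#'   `lambda`, `train_fraction`, `seed`, `train_samples`, `test_samples`.
#' @export
fit_lasso_cox <- function(expr, survival, features = NULL, k_folds = 10,
                          train_fraction = 0.7, seed = 1,
                          lambda_grid = NULL) {
  m <- as_feature_matrix(expr)
  features <- features %||% rownames(m)
  missing_feats <- setdiff(features, rownames(m))
  if (length(missing_feats) > 0) {
    stop_usage(sprintf("feature '%s' not in expression table",
                       missing_feats[1]))
  }
  samples <- intersect(survival$sample_id, colnames(m))
  if (length(samples) < 10) stop_usage("need >= 10 samples with survival data")
  surv <- survival[match(samples, survival$sample_id), ]
  X <- t(m[features, samples, drop = FALSE])

  set.seed(seed)
  n_train <- round(train_fraction * length(samples))
  train <- sort(sample(seq_along(samples), n_train))
  if (sum(surv$event[train]) < 1) stop_usage("no events in the training set")

  ctr <- colMeans(X[train, , drop = FALSE])
  scl <- apply(X[train, , drop = FALSE], 2, sd)
  keep <- scl > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  if (ncol(Xs) == 1) {
    # glmnet needs >= 2 columns; pad with an inert zero column
    Xs <- cbind(Xs, `.dummy` = 0)
  }
  ysurv <- survival::Surv(surv$time, surv$event)

  if (!is.null(lambda_grid) && length(lambda_grid) == 1) {
    fit <- glmnet::glmnet(Xs[train, , drop = FALSE], ysurv[train],
                          family = "cox", alpha = 1, standardize = FALSE,
                          lambda = c(lambda_grid * 1.0001, lambda_grid),
                          thresh = 1e-12)
    lambda <- lambda_grid
    cf <- as.matrix(coef(fit, s = lambda))
  } else {
    foldid <- sample(rep(seq_len(k_folds), length.out = length(train)))
    cv <- glmnet::cv.glmnet(Xs[train, , drop = FALSE], ysurv[train],
                            family = "cox", alpha = 1, standardize = FALSE,
                            nfolds = k_folds, foldid = foldid,
                            lambda = lambda_grid)
    lambda <- cv$lambda.min
    cf <- as.matrix(coef(cv, s = "lambda.min"))
  }
  cfv <- setNames(cf[, 1], rownames(cf))  # vector subset keeps names at n = 1
  zeta_std <- cfv[cfv != 0]
  sel <- setdiff(names(zeta_std), ".dummy")
  zeta_std <- zeta_std[sel]
  structure(
    list(
      features = sel,
      zeta = zeta_std / scl[sel],
      zeta_std = zeta_std,
      lambda = lambda,
      train_fraction = train_fraction,
      seed = seed,
      train_samples = samples[train],
      test_samples = samples[-train]
    ),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d feature(s), lambda = %.4g\n",
              length(x$features), x$lambda))
  if (length(x$features) > 0) {
    print(tibble(feature = x$features, zeta = unname(x$zeta)))
  }
  invisible(x)
}

#' Compute the linear Risk Score
#'
#' `Risk Score = sum_i zeta_i * Exp_i`: the exact dot product of the model
#' coefficients with the expression values, linear in expression.
#'
#' @param model A [fit_lasso_cox()] model, or any list with `features` and
#'   `zeta`.
#' @param expr Wide expression tibble, or a named numeric vector for a
#'   single sample.
#' @return Tibble `sample_id`, `score` (or a single number for a vector
#'   input). A model with no features scores everyone 0.
#' @export
risk_score <- function(model, expr) {
  feats <- model$features
  zeta <- model$zeta
  if (is.numeric(expr)) {
    missing_feats <- setdiff(feats, names(expr))
    if (length(missing_feats) > 0) {
      stop_usage(sprintf("missing feature '%s' in expression vector",
                         missing_feats[1]))
    }
    if (length(feats) == 0) return(0)
    return(sum(zeta * expr[feats]))
  }
  m <- as_feature_matrix(expr)
  missing_feats <- setdiff(feats, rownames(m))
  if (length(missing_feats) > 0) {
    stop_usage(sprintf("missing feature '%s' in expression table",
                       missing_feats[1]))
  }
  score <- if (length(feats) == 0) {
    rep(0, ncol(m))
  } else {
    drop(crossprod(m[feats, , drop = FALSE], zeta))
  }
  tibble(sample_id = colnames(m), score = unname(score))
}

#' Split samples at the median risk score
#'
#' Scores at or below the median go to the `low` group (so exact-median
#' ties and, for odd n, the median sample itself are `low`); group sizes
#' differ by at most one on tie-free input.
#'
#' @param scores Tibble `sample_id`, `score` (or a numeric vector).
#' @return Input with a `group` column (`"low"`/`"high"`), or a character
#'   vector for vector input.
#' @export
stratify_by_median <- function(scores) {
  vec <- if (is.numeric(scores)) scores else scores$score
  med <- median(vec)
  group <- ifelse(vec <= med, "low", "high")
  if (all(group == "low")) warn("all scores at or below the median; single group")
  if (is.numeric(scores)) return(group)
  mutate(scores, group = group)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via `survival::survfit`.
#'
#' @param survival Survival tibble `sample_id`, `time`, `event`.
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(survival) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance; p-value from the
#' chi-square distribution with 1 df. With zero events in both groups the
#' statistic is 0 and p = 1, with a warning.
#'
#' @param group_a,group_b Survival tibbles `sample_id`, `time`, `event`.
#' @return One-row tibble `chi_square`, `p_value`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop_usage("both groups must be non-empty")
  }
  df <- bind_rows(
    mutate(group_a, .group = "a"),
    mutate(group_b, .group = "b")
  )
  if (sum(df$event) == 0) {
    warn("no events in either group; log-rank undefined")
    return(tibble(chi_square = 0, p_value = 1))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ .group,
                               data = df)
  tibble(
    chi_square = sd_fit$chisq,
    p_value = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  )
}

# Censoring-distribution KM evaluated at t (right limit) or t- (left limit).
censoring_km <- function(survival) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                           data = survival)
  ts <- fit$time[fit$n.event > 0]
  ss <- fit$surv[fit$n.event > 0]
  function(t, left = FALSE) {
    vapply(t, function(ti) {
      idx <- if (left) which(ts < ti) else which(ts <= ti)
      if (length(idx) == 0) 1 else ss[max(idx)]
    }, numeric(1))
  }
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative/dynamic AUC: at each evaluation time `t`, cases are samples
#' with an observed event at or before `t`, controls those still at risk
#' after `t`; concordance between risk scores is weighted by the inverse of
#' the Kaplan-Meier censoring survival (`1/G(T_i-)` for cases, `1/G(t)` for
#' controls). Ties in score count 1/2.
#'
#' @param scores Tibble `sample_id`, `score`.
#' @param survival Survival tibble `sample_id`, `time`, `event`.
#' @param eval_times Times at which to evaluate the AUC.
#' @return Tibble `time`, `auc`, `n_cases`, `n_controls`; `auc` is `NA`
#'   (with a warning) when either set is empty.
#' @export
time_dependent_auc <- function(scores, survival, eval_times) {
  df <- inner_join(scores, survival, by = "sample_id")
  if (nrow(df) == 0) stop_usage("no shared samples between scores and survival")
  G <- censoring_km(df)
  out <- purrr::map_dfr(eval_times, function(t) {
    cases <- filter(df, .data$time <= t, .data$event == 1)
    controls <- filter(df, .data$time > t)
    if (nrow(cases) == 0 || nrow(controls) == 0) {
      return(tibble(time = t, auc = NA_real_, n_cases = nrow(cases),
                    n_controls = nrow(controls)))
    }
    wi <- 1 / pmax(G(cases$time, left = TRUE), .Machine$double.eps)
    wj <- rep(1 / pmax(G(t), .Machine$double.eps), nrow(controls))
    cmp <- outer(cases$score, controls$score,
                 function(a, b) (a > b) + 0.5 * (a == b))
    w <- outer(wi, wj)
    tibble(time = t, auc = sum(w * cmp) / sum(w),
           n_cases = nrow(cases), n_controls = nrow(controls))
  })
  if (any(is.na(out$auc))) {
    warn("AUC undefined at some evaluation times (no comparable pairs)")
  }
  out
}

#' Evaluate a risk model on a cohort
#'
#' Convenience wrapper: scores the samples, stratifies at the median,
#' compares the groups by log-rank and returns the KM tables.
#'
#' @param model A [fit_lasso_cox()] model.
#' @param expr Wide expression tibble.
#' @param survival Survival tibble.
#' @param samples Optional subset of samples (e.g. the validation split).
#' @param eval_times Optional times for [time_dependent_auc()].
#' @return List `scores` (with `group`), `logrank`, `km` (per group),
#'   `auc` (or NULL).
#' @export
evaluate_risk_model <- function(model, expr, survival, samples = NULL,
                                eval_times = NULL) {
  sc <- risk_score(model, expr)
  if (!is.null(samples)) sc <- filter(sc, .data$sample_id %in% samples)
  sc <- stratify_by_median(inner_join(sc, select(survival, "sample_id"),
                                      by = "sample_id"))
  surv <- inner_join(select(sc, "sample_id", "group"), survival,
                     by = "sample_id")
  lr <- logrank_test(filter(surv, .data$group == "low"),
                     filter(surv, .data$group == "high"))
  km <- surv |>
    group_by(.data$group) |>
    dplyr::group_modify(~ kaplan_meier(.x)) |>
    ungroup()
  auc <- if (!is.null(eval_times)) {
    time_dependent_auc(select(sc, "sample_id", "score"), survival, eval_times)
  }
  list(scores = sc, logrank = lr, km = km, auc = auc)
}
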