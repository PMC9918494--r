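# broom-style tidiers for the package's fitted objects.

#' Tidy an L0 best-subset fit
#'
#' @param x An `l0_fit` from [l0_path_select()].
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `p.value`.
#' @export
tidy.l0_fit <- function(x, ...) {
  tibble(
    term = names(x$beta) %||% character(0),
    estimate = unname(x$beta),
    p.value = unname(x$tf_p_values)
  )
}

#' @rdname tidy.l0_fit
#' @export
glance.l0_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, gamma = x$gamma,
    n_selected = length(x$support), nobs = x$n
  )
}

#' Tidy a Lasso-Cox risk model
#'
#' @param x A `risk_model` from [fit_lasso_cox()].
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (input scale), `estimate_std`.
#' @export
tidy.risk_model <- function(x, ...) {
  tibble(
    term = x$features,
    estimate = unname(x$zeta),
    estimate_std = unname(x$zeta_std)
  )
}

#' @rdname tidy.risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble(
    n_features = length(x$features), lambda = x$lambda,
    train_fraction = x$train_fraction,
    n_train = length(x$train_samples), n_test = length(x$test_samples)
  )
}

#' Tidy a consensus clustering result
#'
#' @param x A `consensus_result` from [consensus_cluster()].
#' @param ... Unused.
#' @return The per-sample label tibble.
#' @export
tidy.consensus_result <- function(x, ...) x$labels

#' @rdname tidy.consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(rank = x$rank, cophenetic = x$cophenetic, silhouette = x$silhouette)
}
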