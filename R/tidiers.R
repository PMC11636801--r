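#' Tidy a fitted count model
#'
#' One row per estimated quantity: intercept, coefficients of included
#' factors, scale parameters of random-parameter distributions, and the
#' dispersion parameter when present.
#'
#' @param x A `count_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `role`, `factor`, `transformation`,
#'   `distribution`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy count_fit
#' @export
tidy.count_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a fitted count model
#'
#' @param x A `count_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `logLik`, `zeta`, `BIC`, `AIC`,
#'   `objective`, `converged`, `nobs`, `hdraws`, `se_method`.
#' @method glance count_fit
#' @export
glance.count_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, zeta = x$zeta,
                 BIC = x$bic %||% NA_real_, AIC = x$aic %||% NA_real_,
                 objective = x$objective, converged = x$converged,
                 nobs = x$n, hdraws = x$hdraws, se_method = x$se_method)
}

#' Tidy a search result (the convergence trajectory)
#'
#' @param x A `count_search`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `incumbent`, `best`, `accepted`;
#'   iteration 0 rows are the initialization (initial solution first).
#' @method tidy count_search
#' @export
tidy.count_search <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a search run
#'
#' @param x A `count_search`.
#' @param ... Unused.
#' @method glance count_search
#' @export
glance.count_search <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, objective_kind = x$config$objective,
                 best_objective = x$best_objective,
                 evaluations = x$evaluations, cache_hits = x$cache_hits,
                 wall_time = x$wall_time, seed = x$config$seed)
}
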