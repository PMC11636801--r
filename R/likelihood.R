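#' Model-type decision set
#'
#' The candidate probabilistic models: Poisson (no dispersion parameter),
#' negative binomial (NB2) and Famoye's restricted generalized Poisson, both
#' of which carry a dispersion parameter `phi > 0` and collapse to Poisson as
#' `phi -> 0`.
#'
#' @return Character vector of model-type names.
#' @export
cs_model_types <- function() c("Poisson", "NB", "GP")

#' Does a model type carry a dispersion parameter?
#' @param model Model-type name.
#' @export
has_dispersion <- function(model) {
  model <- match.arg(model, cs_model_types())
  model != "Poisson"
}

#' Conditional mean (rate) of the count process
#'
#' `lambda_i = exp(X_i beta + offset_i)`, clamped to `[1e-10, 1e10]` to keep
#' the optimizer inside a finite region. Random-parameter heterogeneity
#' enters through the `beta` draws; the model error of the NB/GP forms is
#' absorbed by their closed-form pmfs.
#'
#' @param X Design matrix (rows = observations).
#' @param beta Coefficient vector (or matrix with one column per draw).
#' @param offset Optional log-exposure offset vector.
#' @return Vector (or matrix) of positive rates.
#' @export
rate <- function(X, beta, offset = NULL) {
  eta <- X %*% beta
  if (!is.null(offset)) eta <- eta + offset
  clamp_rate(exp(eta))
}

clamp_rate <- function(lambda) pmin(pmax(lambda, 1e-10), 1e10)

#' Count probability mass function
#'
#' Closed-form pmfs, computed in log space with log-gamma terms:
#'
#' * Poisson: `exp(-lambda) lambda^y / y!`;
#' * NB2: `(r/(r+lambda))^r * Gamma(r+y)/(Gamma(r) y!) * (lambda/(r+lambda))^y`
#'   with `r = 1/phi`;
#' * GP (Famoye's restricted form):
#'   `(lambda/(1+phi*lambda))^y (1+phi*y)^(y-1)/y! *
#'    exp(-lambda (1+phi*y)/(1+phi*lambda))`.
#'
#' Both dispersed forms are numerically stable as `phi -> 0`, where they
#' collapse to the Poisson pmf.
#'
#' @param y Non-negative integer counts.
#' @param lambda Positive rate(s).
#' @param phi Dispersion parameter (ignored for Poisson).
#' @param model Model-type name.
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities) recycled to the common length.
#' @examples
#' count_pmf(0, 1, model = "Poisson")        # exp(-1)
#' count_pmf(0, 1, phi = 1, model = "NB")    # 0.5
#' @export
count_pmf <- function(y, lambda, phi = 0, model = c("Poisson", "NB", "GP"), log = FALSE) {
  model <- match.arg(model)
  if (any(y < 0 | y != round(y))) cs_abort("y must be non-negative integers",
                                           "countspec_validation_error")
  if (model != "Poisson" && (length(phi) != 1L || phi < 0)) {
    cs_abort("phi must be a non-negative scalar for NB/GP", "countspec_validation_error")
  }
  lp <- switch(model,
    Poisson = dpois(y, lambda, log = TRUE),
    NB = {
      # below phi ~ 1e-9 the lgamma(1/phi + y) - lgamma(1/phi) difference
      # cancels catastrophically in double precision; use the Poisson limit
      if (phi < 1e-9) dpois(y, lambda, log = TRUE) else {
        r <- 1 / phi
        lgamma(r + y) - lgamma(r) - lfactorial(y) +
          r * (log(r) - log(r + lambda)) + y * (log(lambda) - log(r + lambda))
      }
    },
    GP = {
      y * (log(lambda) - log1p(phi * lambda)) + (y - 1) * log1p(phi * y) -
        lfactorial(y) - lambda * (1 + phi * y) / (1 + phi * lambda)
    }
  )
  if (log) lp else exp(lp)
}

#' Simulated log-likelihood
#'
#' The maximum-simulated-likelihood objective
#' `ln L = sum_i ln[(1/H) sum_h P(y_i | lambda_i^(h), m)]`, where for each
#' Halton draw `h` the random coefficients are
#' `beta_k^(h) = b_k + deviate(f_k, u[i,h,k], omega_k)` and fixed coefficients
#' are `b_k`. With zero random parameters this reduces exactly to the
#' closed-form log-likelihood (the H-average of a constant).
#'
#' @param dataset A [count_dataset()].
#' @param design A feasible design from [build_design()].
#' @param spec The [specification()] being estimated.
#' @param params Named list: `b` (coefficients, intercept first, in design
#'   column order), `omega` (scales for random factors, in factor order),
#'   `phi` (dispersion, required for NB/GP).
#' @param draws A [halton_draws()] object with at least as many dimensions as
#'   the specification has random parameters; ignored when there are none.
#' @param centered Passed to [mixing_deviate()].
#' @return The simulated log-likelihood (scalar; `-Inf`/non-finite values
#'   signal an estimation failure for this parameter vector).
#' @export
simulated_loglik <- function(dataset, design, spec, params, draws = NULL,
                             centered = FALSE) {
  stopifnot(design$feasible)
  y <- dataset$response
  X <- design$X
  b <- params$b
  if (length(b) != ncol(X)) cs_abort("length(b) must match design columns",
                                     "countspec_validation_error")
  eta0 <- drop(X %*% b)
  if (!is.null(dataset$offset)) eta0 <- eta0 + dataset$offset

  rnd <- names(spec$rand)[spec$rand == 1L]
  model <- spec$model
  phi <- if (has_dispersion(model)) params$phi else 0

  if (length(rnd) == 0L) {
    lp <- count_pmf(y, clamp_rate(exp(eta0)), phi, model, log = TRUE)
    return(sum(lp))
  }

  if (is.null(draws) || draws$n_dims < length(rnd) || draws$n_obs != dataset$n) {
    cs_abort("draw set does not cover the random-parameter dimensions",
             "countspec_validation_error")
  }
  H <- draws$n_draws
  eta <- matrix(eta0, nrow = dataset$n, ncol = H)
  for (d in seq_along(rnd)) {
    k <- rnd[d]
    om <- abs(params$omega[d])
    xk <- design$X[, k]
    dev <- matrix(mixing_deviate(spec$dist[[k]], as.vector(draws$u[, , d]), om,
                                 centered = centered),
                  nrow = dataset$n, ncol = H)
    eta <- eta + xk * dev
  }
  lam <- clamp_rate(exp(eta))
  lp <- matrix(count_pmf(rep(y, H), as.vector(lam), phi, model, log = TRUE),
               nrow = dataset$n, ncol = H)
  sum(log_mean_exp_rows(lp))
}

#' Information criterion for model selection
#'
#' All criteria are oriented for minimization: `BIC = -2 lnL + zeta * ln(n)`,
#' `AIC = -2 lnL + 2 zeta`, and `LL` returns `-lnL`. `zeta` tallies the
#' estimated parameters: `sum_k(alpha_k + r_k) + q` plus 1 for the
#' always-present intercept, where `q = 1` when the model carries a
#' dispersion parameter.
#'
#' @param loglik Log-likelihood.
#' @param zeta Number of estimated parameters.
#' @param n_obs Number of observations.
#' @param kind One of `"BIC"`, `"AIC"`, `"LL"`.
#' @return Scalar criterion value.
#' @examples
#' information_criterion(-100, 5, 100)            # 200 + 5*log(100)
#' information_criterion(-100, 5, 100, "AIC")     # 210
#' @export
information_criterion <- function(loglik, zeta, n_obs, kind = c("BIC", "AIC", "LL")) {
  kind <- match.arg(kind)
  if (n_obs < 1) cs_abort("n_obs must be >= 1", "countspec_validation_error")
  switch(kind,
    BIC = -2 * loglik + zeta * log(n_obs),
    AIC = -2 * loglik + 2 * zeta,
    LL = -loglik
  )
}

# zeta per the constraint system: sum(alpha + r) + dispersion flag + intercept
spec_zeta <- function(spec) {
  sum(spec$alpha) + sum(spec$rand) + as.integer(has_dispersion(spec$model)) + 1L
}
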