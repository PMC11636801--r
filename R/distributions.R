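#' Mixing-distribution decision set
#'
#' The candidate mixing laws for random parameters, in the fixed order used
#' for index arithmetic by the discrete metaheuristics.
#'
#' @return Character vector of distribution names.
#' @export
cs_distributions <- function() {
  c("gamma", "uniform", "normal", "triangular", "lindley")
}

#' Random-parameter deviate from a uniform draw
#'
#' Deterministic quantile map from a uniform (0,1) draw to a mixing-law
#' deviate with scale `omega`, the building block of the random coefficient
#' `beta_k = b_k + f_k(omega_k)`:
#'
#' * `normal` — `omega * qnorm(u)` (mean 0, sd `omega`);
#' * `uniform` — `omega * (2u - 1)` (symmetric on `[-omega, omega]`);
#' * `triangular` — `omega` times the symmetric triangular quantile on
#'   `[-1, 1]`;
#' * `gamma` — `qgamma(u, shape = omega, scale = 1)`, a strictly positive
#'   additive deviate;
#' * `lindley` — the Lindley(`theta = omega`) quantile, computed by
#'   closed-form inversion via the Lambert W (-1 branch); also strictly
#'   positive, with the long right tail that lets some observations carry
#'   much larger effects.
#'
#' The positive laws (gamma, Lindley) enter uncentered by default, consistent
#' with the additive coefficient formulation; set `centered = TRUE` to
#' subtract their analytic mean.
#'
#' @param dist Distribution name, one of [cs_distributions()].
#' @param u Uniform draws, strictly inside (0, 1).
#' @param omega Non-negative scale parameter.
#' @param centered Subtract the analytic mean of the positive laws?
#' @return Numeric vector of deviates, same length as `u`.
#' @examples
#' mixing_deviate("normal", 0.5, 1)    # 0
#' mixing_deviate("uniform", 0.75, 2)  # 1
#' @export
mixing_deviate <- function(dist, u, omega, centered = FALSE) {
  dist <- match.arg(dist, cs_distributions())
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega < 0) {
    cs_abort("omega must be a non-negative scalar", "countspec_validation_error")
  }
  if (any(u <= 0 | u >= 1)) cs_abort("uniform draws must lie strictly in (0,1)",
                                     "countspec_validation_error")
  out <- switch(dist,
    normal = omega * qnorm(u),
    uniform = omega * (2 * u - 1),
    triangular = omega * qtri_sym(u),
    gamma = if (omega == 0) rep(0, length(u)) else qgamma(u, shape = omega, scale = 1),
    lindley = if (omega == 0) rep(0, length(u)) else qlindley(u, omega)
  )
  if (centered && dist %in% c("gamma", "lindley") && omega > 0) {
    mu <- switch(dist, gamma = omega, lindley = (omega + 2) / (omega * (omega + 1)))
    out <- out - mu
  }
  out
}

# symmetric triangular quantile on [-1, 1]
qtri_sym <- function(u) {
  ifelse(u < 0.5, sqrt(2 * u) - 1, 1 - sqrt(2 * (1 - u)))
}

#' Lindley distribution quantile
#'
#' Closed-form inverse of the Lindley CDF
#' `F(x) = 1 - (1 + theta * x / (1 + theta)) * exp(-theta * x)` via the
#' `W_{-1}` branch of the Lambert W function:
#' `Q(u) = -1 - 1/theta - W_{-1}((1 + theta)(u - 1) exp(-(1 + theta))) / theta`.
#'
#' @param u Probabilities in (0, 1).
#' @param theta Positive rate parameter.
#' @return Quantiles (non-negative).
#' @export
qlindley <- function(u, theta) {
  stopifnot(theta > 0)
  z <- (1 + theta) * (u - 1) * exp(-(1 + theta))
  pmax(-1 - 1 / theta - lambert_wm1(z) / theta, 0)
}

#' Lindley distribution CDF
#' @param x Quantiles (`x >= 0`).
#' @param theta Positive rate parameter.
#' @export
plindley <- function(x, theta) {
  stopifnot(theta > 0)
  ifelse(x < 0, 0, 1 - (1 + theta * x / (1 + theta)) * exp(-theta * x))
}

# Lambert W, branch -1, for z in [-1/e, 0): w * exp(w) = z with w <= -1.
# Vectorized Newton iteration from the asymptotic seed w0 = log(-z) - log(-log(-z)).
lambert_wm1 <- function(z) {
  if (any(z < -exp(-1) - 1e-12 | z >= 0)) {
    cs_abort("lambert_wm1 defined on [-1/e, 0)", "countspec_validation_error")
  }
  z <- pmax(z, -exp(-1))
  L1 <- log(-z)
  w <- L1 - log(-L1)
  for (i in 1:60) {
    ew <- exp(w)
    f <- w * ew - z
    step <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))  # Halley
    step[!is.finite(step)] <- 0
    w <- w - step
    if (max(abs(step)) < 1e-14) break
  }
  # exact at the branch point
  w[z == -exp(-1)] <- -1
  w
}
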