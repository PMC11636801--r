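#' Describe a synthetic data-generating truth
#'
#' The generating process for recovery experiments: cross-sectional counts
#' from `lambda_i = exp(b0 + sum_k beta_ik x_ik)` with a constant, fixed
#' effects, random parameters (segment-level heterogeneity with a chosen
#' mixing law), plus pure-noise columns whose true coefficient is exactly
#' zero. Counts are simulated `n_reps` times and averaged, and the rounded
#' averages serve as the "true" counts of the experimental dataset.
#'
#' The default truth mirrors the reference design: 2,000 observations, three
#' fixed effects, two normally distributed random parameters, five noise
#' factors, Poisson counts, 100 repetitions. Covariates are independent
#' standard normal, and the default slope/scale magnitudes follow the
#' published estimate pattern rescaled to unit linear-predictor variance (see
#' the methods vignette); they are estimates-as-truth, not anyone's original
#' generating values.
#'
#' @param n_obs Number of observations.
#' @param intercept True constant `b0`.
#' @param fixed Named numeric vector of fixed-effect coefficients.
#' @param random Data frame with columns `name`, `mean`, `omega`, `dist`
#'   describing the random parameters.
#' @param n_noise Number of pure-noise factors (true coefficient 0).
#' @param model Count model generating the data: `"Poisson"`, `"NB"`, `"GP"`.
#' @param phi Dispersion for NB/GP truths.
#' @param n_reps Repetitions over which counts are averaged.
#' @param covariate_sd Standard deviation of the (normal) covariates.
#' @param redraw_random Redraw the random-parameter deviates at every
#'   repetition (washes heterogeneity out of the averaged counts) instead of
#'   holding them fixed per observation.
#' @return Object of class `cs_truth`.
#' @export
synthetic_truth <- function(n_obs = 2000,
                            intercept = 2.19,
                            fixed = NULL,
                            random = NULL,
                            n_noise = 5,
                            model = "Poisson", phi = NULL,
                            n_reps = 100, covariate_sd = 1,
                            redraw_random = FALSE) {
  if (is.null(fixed) || is.null(random)) {
    # published estimate pattern (three fixed, two normal RPs; the triangular
    # scale converted to its implied sd), rescaled to unit lp variance
    raw <- c(-1.02, 2.65, -2.66, -2.87, -1.25, 4.01 / sqrt(6), 0.93)
    sc <- raw / sqrt(sum(raw^2))
    if (is.null(fixed)) fixed <- setNames(sc[1:3], paste0("FIXED", 1:3))
    if (is.null(random)) {
      random <- tibble::tibble(name = c("RANDOM1", "RANDOM2"),
                               mean = sc[4:5], omega = abs(sc[6:7]),
                               dist = "normal")
    }
  }
  random <- tibble::as_tibble(random)
  # omega = 0 is admitted as the degenerate no-heterogeneity limit
  stopifnot(all(c("name", "mean", "omega", "dist") %in% names(random)),
            all(random$omega >= 0), all(random$dist %in% cs_distributions()),
            n_obs >= 1, n_reps >= 1)
  model <- match.arg(model, cs_model_types())
  if (has_dispersion(model) && (is.null(phi) || phi <= 0)) {
    cs_abort("NB/GP truths need phi > 0", "countspec_config_error")
  }
  structure(list(n_obs = n_obs, intercept = intercept, fixed = fixed,
                 random = random, n_noise = n_noise, model = model, phi = phi,
                 n_reps = n_reps, covariate_sd = covariate_sd,
                 redraw_random = redraw_random),
            class = "cs_truth")
}

#' Generate a synthetic dataset from a truth
#'
#' Draws independent normal covariates, forms the observation-level random
#' coefficients `beta_ik = mean_k + deviate(dist_k, omega_k)` (held fixed
#' across repetitions unless `redraw_random`), computes the rates, simulates
#' counts `n_reps` times from the truth's model, and returns the rounded mean
#' counts as the response, together with the truth for recovery scoring.
#' Bit-reproducible for a fixed seed.
#'
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed.
#' @return List with elements `dataset` (a [count_dataset()]) and `truth`.
#' @export
generate_synthetic <- function(truth = synthetic_truth(), seed = 1) {
  stopifnot(inherits(truth, "cs_truth"))
  # independent substreams for covariates / heterogeneity / count noise, so
  # degenerate settings (omega = 0) reproduce the no-heterogeneity dataset
  seeds <- derive_seeds(seed, 3)
  n <- truth$n_obs
  k_fixed <- names(truth$fixed)
  k_rand <- truth$random$name
  k_noise <- if (truth$n_noise > 0) paste0("NOISE", seq_len(truth$n_noise)) else character(0)
  cols <- c(k_fixed, k_rand, k_noise)
  set.seed(seeds[1])
  X <- matrix(rnorm(n * length(cols), sd = truth$covariate_sd), n,
              dimnames = list(NULL, cols))

  eta_fixed <- truth$intercept + drop(X[, k_fixed, drop = FALSE] %*% truth$fixed)

  draw_rand_eta <- function() {
    eta <- numeric(n)
    for (r in seq_len(nrow(truth$random))) {
      b <- truth$random$mean[r] +
        mixing_deviate(truth$random$dist[r], runif(n), truth$random$omega[r])
      eta <- eta + X[, k_rand[r]] * b
    }
    eta
  }

  set.seed(seeds[2])
  rand_eta <- if (nrow(truth$random) > 0 && !truth$redraw_random) draw_rand_eta() else NULL
  set.seed(seeds[3])
  draw_counts <- function() {
    eta <- eta_fixed +
      if (nrow(truth$random) == 0) 0
      else if (truth$redraw_random) draw_rand_eta()
      else rand_eta
    lam <- exp(eta)
    if (any(!is.finite(lam)) || any(lam > 1e8)) {
      cs_abort("rate overflow under the supplied coefficients; rescale covariates or coefficients",
               "countspec_validation_error")
    }
    switch(truth$model,
      Poisson = rpois(n, lam),
      NB = rnbinom(n, size = 1 / truth$phi, mu = lam),
      GP = rgpois(n, lam, truth$phi)
    )
  }

  acc <- numeric(n)
  for (rep in seq_len(truth$n_reps)) acc <- acc + draw_counts()
  y <- as.integer(round(acc / truth$n_reps))

  df <- tibble::as_tibble(as.data.frame(X))
  df$Y <- y
  list(dataset = count_dataset(df, "Y"), truth = truth)
}

# generalized Poisson sampler by pmf inversion (restricted form, phi >= 0)
rgpois <- function(n, lambda, phi) {
  lambda <- rep_len(lambda, n)
  u <- runif(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    ymax <- max(50, ceiling(lambda[i] * (1 + phi * lambda[i])^2 * 10))
    cdf <- cumsum(count_pmf(0:ymax, lambda[i], phi, "GP"))
    out[i] <- findInterval(u[i], cdf)
  }
  out
}

#' The generating specification of a truth
#' @param truth A [synthetic_truth()].
#' @param space Optional [search_space()] to normalize against.
#' @export
truth_spec <- function(truth, space = NULL) {
  k_noise <- if (truth$n_noise > 0) paste0("NOISE", seq_len(truth$n_noise)) else character(0)
  factors <- c(names(truth$fixed), truth$random$name, k_noise)
  sp <- specification(factors,
                      include = c(names(truth$fixed), truth$random$name),
                      random = truth$random$name,
                      distribution = setNames(truth$random$dist, truth$random$name),
                      model = truth$model)
  if (!is.null(space)) sp <- normalize_spec(sp, space)
  sp
}

#' Score how well a result recovers a synthetic truth
#'
#' Compares a fitted model (or the best model of a search) against the
#' generating truth: model-type match, inclusion of every true factor, false
#' inclusion of noise factors, detection of each random parameter and whether
#' its distribution matches exactly or is merely "shape-confusable" (a
#' symmetric law recovered as another symmetric law, e.g. normal vs
#' triangular), and coefficient errors in estimated-standard-error units.
#'
#' @param result A `count_fit` or `count_search`.
#' @param truth The [synthetic_truth()] that generated the data.
#' @return Object of class `cs_recovery`: a list with fields `model_match`,
#'   `true_included` (named logical), `all_true_included`,
#'   `false_inclusions`, `random_detected` (named logical), `dist_match`,
#'   `shape_confusable`, and `coef_errors` (tibble of truth vs estimate with
#'   `se_units`).
#' @export
score_recovery <- function(result, truth) {
  fit <- if (inherits(result, "count_search")) result$best_fit else result
  stopifnot(inherits(fit, "count_fit"), inherits(truth, "cs_truth"))
  spec <- fit$spec
  k_true <- c(names(truth$fixed), truth$random$name)
  k_noise <- if (truth$n_noise > 0) paste0("NOISE", seq_len(truth$n_noise)) else character(0)

  true_included <- setNames(spec$alpha[k_true] == 1L, k_true)
  false_inc <- sum(spec$alpha[k_noise] == 1L)
  rand_detected <- setNames(spec$rand[truth$random$name] == 1L, truth$random$name)
  symmetric <- c("normal", "triangular", "uniform")
  dist_match <- logical(nrow(truth$random))
  shape_conf <- logical(nrow(truth$random))
  for (r in seq_len(nrow(truth$random))) {
    k <- truth$random$name[r]
    if (rand_detected[[k]]) {
      found <- spec$dist[[k]]
      want <- truth$random$dist[r]
      dist_match[r] <- found == want
      shape_conf[r] <- !dist_match[r] &&
        ((found %in% symmetric) == (want %in% symmetric))
    }
  }

  truth_coef <- tibble::tibble(
    factor = c(NA_character_, names(truth$fixed), truth$random$name),
    term = c("(Intercept)", names(truth$fixed), truth$random$name),
    truth = c(truth$intercept, unname(truth$fixed), truth$random$mean))
  est <- fit$coefficients[fit$coefficients$role %in% c("intercept", "coefficient"),
                          c("term", "estimate", "std.error")]
  coef_errors <- dplyr::inner_join(truth_coef, est, by = "term")
  coef_errors$se_units <- (coef_errors$estimate - coef_errors$truth) / coef_errors$std.error

  structure(list(model_match = spec$model == truth$model,
                 true_included = true_included,
                 all_true_included = all(true_included),
                 false_inclusions = false_inc,
                 random_detected = rand_detected,
                 dist_match = setNames(dist_match, truth$random$name),
                 shape_confusable = setNames(shape_conf, truth$random$name),
                 coef_errors = coef_errors),
            class = "cs_recovery")
}

#' @export
print.cs_recovery <- function(x, ...) {
  cat("<recovery report>\n")
  cat(sprintf("  model type match: %s\n", x$model_match))
  cat(sprintf("  true factors included: %d/%d\n", sum(x$true_included),
              length(x$true_included)))
  cat(sprintf("  noise factors falsely included: %d\n", x$false_inclusions))
  cat(sprintf("  random parameters detected: %d/%d (exact dist %d, shape-confusable %d)\n",
              sum(x$random_detected), length(x$random_detected),
              sum(x$dist_match), sum(x$shape_confusable)))
  if (nrow(x$coef_errors)) {
    cat(sprintf("  max |coefficient error|: %.2f SE units\n",
                max(abs(x$coef_errors$se_units), na.rm = TRUE)))
  }
  invisible(x)
}
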