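# Deterministic fixtures shared across the suite. Everything is generated in
# code; nothing is read from disk.

# small Poisson dataset with two informative factors and one pure-noise column
make_poisson_data <- function(n = 80, seed = 7, b0 = 0.5, bA = 0.8, bB = -0.5) {
  set.seed(seed)
  df <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  df$y <- rpois(n, exp(b0 + bA * df$A + bB * df$B))
  count_dataset(df, "y")
}

# dataset with genuine normal random-parameter heterogeneity on C
make_mixed_data <- function(n = 200, seed = 11, omega = 0.5) {
  set.seed(seed)
  df <- data.frame(A = rnorm(n), C = rnorm(n))
  beta_c <- 0.5 + omega * rnorm(n)
  df$y <- rpois(n, exp(0.8 + 0.6 * df$A + beta_c * df$C))
  count_dataset(df, "y")
}

# a tiny fully enumerable space: fixed effects only, identity transform
make_tiny_space <- function(dataset, models = "Poisson") {
  search_space(dataset, models = models, distributions = "normal",
               transformations = "identity")
}

# scaled synthetic truth used by the recovery experiments: 2 fixed effects,
# 1 normal random parameter, 3 noise factors, n = 500
make_recovery_truth <- function(n_obs = 500) {
  synthetic_truth(
    n_obs = n_obs, intercept = 1.0,
    fixed = c(FIXED1 = 0.6, FIXED2 = -0.4),
    random = data.frame(name = "RANDOM1", mean = 0.5, omega = 0.4,
                        dist = "normal"),
    n_noise = 3, model = "Poisson", n_reps = 100)
}

expect_spec_valid <- function(spec, space) {
  expect_true(all(spec$alpha >= spec$rand))
  expect_true(spec$model %in% space$models)
  ps <- space$prespec
  if (length(ps$include)) {
    expect_identical(unname(spec$alpha[names(ps$include)]), as.integer(ps$include))
  }
  if (length(ps$random)) {
    expect_identical(unname(spec$rand[names(ps$random)]), as.integer(ps$random))
  }
  if (!is.null(ps$model)) expect_identical(spec$model, ps$model)
  # canonical inactive genes
  expect_true(all(spec$trans[spec$alpha == 0L] %in%
                    c("identity", ps$transformation)))
}
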