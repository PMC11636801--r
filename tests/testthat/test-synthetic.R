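test_that("the default truth yields the reference design shape", {
  gen <- generate_synthetic(synthetic_truth(), seed = 1)
  d <- gen$dataset
  expect_equal(d$n, 2000)
  expect_equal(length(factor_names(d)), 10)  # 3 fixed + 2 random + 5 noise
  expect_setequal(factor_names(d),
                  c(paste0("FIXED", 1:3), paste0("RANDOM", 1:2),
                    paste0("NOISE", 1:5)))
  expect_true(all(d$response >= 0))
})

test_that("a null truth produces unit mean counts within Monte Carlo error", {
  truth <- synthetic_truth(n_obs = 3000, intercept = 0,
                           fixed = c(X1 = 0), random = data.frame(
                             name = character(), mean = numeric(),
                             omega = numeric(), dist = character()),
                           n_noise = 2, n_reps = 20)
  gen <- generate_synthetic(truth, seed = 3)
  # E[y] = exp(0) = 1; averaged counts have var ~ 1/(n_reps) per obs
  mc_se <- sqrt(1 / (20 * 3000))
  expect_lt(abs(mean(gen$dataset$response) - 1), 3 * mc_se + 0.5 / 20)
})

test_that("omega = 0 reproduces the dataset of the purely fixed truth", {
  t_rand <- synthetic_truth(n_obs = 200, intercept = 0.5,
                            fixed = c(F1 = 0.4),
                            random = data.frame(name = "R1", mean = 0.3,
                                                omega = 0, dist = "normal"),
                            n_noise = 1, n_reps = 10)
  t_fixed <- synthetic_truth(n_obs = 200, intercept = 0.5,
                             fixed = c(F1 = 0.4, R1 = 0.3),
                             random = data.frame(name = character(),
                                                 mean = numeric(),
                                                 omega = numeric(),
                                                 dist = character()),
                             n_noise = 1, n_reps = 10)
  g1 <- generate_synthetic(t_rand, seed = 8)
  g2 <- generate_synthetic(t_fixed, seed = 8)
  expect_identical(g1$dataset$response, g2$dataset$response)
  expect_equal(g1$dataset$factors$R1, g2$dataset$factors$R1)
})

test_that("generation is bit-reproducible and averaging shrinks variance", {
  truth <- make_recovery_truth(300)
  g1 <- generate_synthetic(truth, seed = 4)
  g2 <- generate_synthetic(truth, seed = 4)
  expect_identical(g1$dataset$response, g2$dataset$response)

  t1 <- truth; t1$n_reps <- 1
  single <- generate_synthetic(t1, seed = 4)
  # same covariates and heterogeneity (paired seed), only count noise differs
  resid_avg <- g1$dataset$response
  resid_one <- single$dataset$response
  expect_identical(g1$dataset$factors, single$dataset$factors)
  expect_lt(var(resid_avg - resid_one) + 1e-9, 2 * var(resid_one))
  # direct check: conditional variance around the heterogeneous mean
  expect_lt(var(resid_avg), var(resid_one) + 1e-9)
})

test_that("rate overflow is caught with advice", {
  truth <- synthetic_truth(n_obs = 50, intercept = 25,
                           fixed = c(F1 = 10),
                           random = data.frame(name = character(),
                                               mean = numeric(),
                                               omega = numeric(),
                                               dist = character()),
                           n_noise = 0, n_reps = 2)
  expect_error(generate_synthetic(truth, seed = 1), "rescale",
               class = "countspec_validation_error")
})

test_that("recovery scoring flags hits, misses and shape confusion", {
  truth <- make_recovery_truth(400)
  gen <- generate_synthetic(truth, seed = 21)
  sp_true <- truth_spec(truth)
  f <- fit_spec(gen$dataset, sp_true, hdraws = 100)
  rec <- score_recovery(f, truth)
  expect_true(rec$model_match)
  expect_true(rec$all_true_included)
  expect_equal(rec$false_inclusions, 0)
  expect_true(all(rec$random_detected))
  expect_true(all(rec$dist_match))

  # drop the random parameter: flagged as a missed random effect
  sp_norand <- sp_true; sp_norand$rand["RANDOM1"] <- 0L
  f2 <- fit_spec(gen$dataset, countspec:::canonicalize_bare(sp_norand))
  rec2 <- score_recovery(f2, truth)
  expect_false(any(rec2$random_detected))

  # triangular instead of normal: shape-confusable, not an exact match
  sp_tri <- sp_true; sp_tri$dist["RANDOM1"] <- "triangular"
  f3 <- fit_spec(gen$dataset, sp_tri, hdraws = 100)
  rec3 <- score_recovery(f3, truth)
  expect_false(any(rec3$dist_match))
  expect_true(all(rec3$shape_confusable))
})

test_that("removing a noise factor does not worsen the objective on average", {
  truth <- make_recovery_truth(300)
  deltas <- numeric(4)
  for (s in seq_len(4)) {
    gen <- generate_synthetic(truth, seed = 40 + s)
    base <- truth_spec(truth)
    with_noise <- base; with_noise$alpha["NOISE1"] <- 1L
    f_base <- fit_spec(gen$dataset, base, hdraws = 60)
    f_noise <- fit_spec(gen$dataset, countspec:::canonicalize_bare(with_noise),
                        hdraws = 60)
    deltas[s] <- f_noise$objective - f_base$objective
  }
  expect_gt(mean(deltas), 0)
})
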