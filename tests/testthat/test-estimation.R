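test_that("intercept-only Poisson fit recovers the closed-form MLE", {
  d <- count_dataset(data.frame(y = c(1, 2, 3), A = c(0, 1, 0)), "y")
  f <- fit_spec(d, specification("A"))
  # lambda-hat = mean(y) = 2; lnL = sum(y) log 2 - 6 - log(1! 2! 3!)
  expect_equal(f$coefficients$estimate[1], log(2), tolerance = 1e-6)
  expect_equal(f$loglik, 6 * log(2) - 6 - log(12), tolerance = 1e-6)
  expect_equal(f$zeta, 1)
  expect_equal(f$objective,
               information_criterion(f$loglik, f$zeta, 3, "BIC"))
})

test_that("fixed-effect fits and standard errors agree with glm", {
  d <- make_poisson_data(150)
  sp <- specification(c("A", "B", "C"), include = c("A", "B"))
  f <- fit_spec(d, sp)
  g <- glm(d$response ~ d$factors$A + d$factors$B, family = poisson())
  expect_equal(unname(f$coefficients$estimate), unname(coef(g)), tolerance = 1e-4)
  expect_equal(unname(f$coefficients$std.error),
               unname(summary(g)$coefficients[, 2]), tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("fits are bit-reproducible for identical inputs", {
  d <- make_mixed_data(80)
  sp <- specification(c("A", "C"), include = c("A", "C"), random = "C",
                      distribution = c(C = "normal"))
  f1 <- fit_spec(d, sp, hdraws = 50)
  f2 <- fit_spec(d, sp, hdraws = 50)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("an infeasible design yields +Inf objective without error", {
  d <- count_dataset(data.frame(y = 1:4, A = c(0, 1, 2, 3)), "y")
  sp <- specification("A", include = "A", transformation = c(A = "ln"))
  f <- fit_spec(d, sp)
  expect_false(f$converged)
  expect_identical(f$objective, Inf)
})

test_that("a spurious random parameter shrinks toward zero and costs BIC", {
  # equidispersed data: true omega = 0
  d <- make_mixed_data(300, seed = 5, omega = 0)
  sp_fix <- specification(c("A", "C"), include = c("A", "C"))
  sp_rnd <- specification(c("A", "C"), include = c("A", "C"), random = "C",
                          distribution = c(C = "normal"))
  f_fix <- fit_spec(d, sp_fix)
  f_rnd <- fit_spec(d, sp_rnd, hdraws = 100)
  om <- f_rnd$coefficients$estimate[f_rnd$coefficients$role == "scale"]
  expect_lt(abs(om), 0.1)
  expect_gt(f_rnd$objective, f_fix$objective)
})

test_that("the estimator is calibrated on model-consistent data", {
  # raw single-repetition counts match the fitted model exactly, so the
  # 2-SE interval should have roughly nominal (~95%) per-coefficient
  # coverage; 0.8 is a loose lower bound allowing binomial noise at
  # 8 seeds x 4 coefficients plus simulation chatter
  truth <- make_recovery_truth()
  truth$n_reps <- 1
  z <- c()
  for (s in seq_len(8)) {
    gen <- generate_synthetic(truth, seed = 100 + s)
    f <- fit_spec(gen$dataset, truth_spec(truth), hdraws = 100)
    z <- c(z, score_recovery(f, truth)$coef_errors$se_units)
  }
  expect_gte(mean(abs(z) <= 2), 0.8)
  # and the point estimates themselves are accurate
  expect_lt(max(abs(z)) , 6)
})

test_that("repair leaves fully significant models untouched", {
  d <- make_poisson_data(200)
  sp <- specification(c("A", "B", "C"), include = c("A", "B"))
  f <- repair_spec(d, sp)
  expect_identical(f$spec$alpha, sp$alpha)
  co <- f$coefficients
  expect_true(all(co$p.value[co$role %in% c("coefficient", "scale")] <= 0.1))
})

test_that("repair drops the single worst insignificant term per pass", {
  d <- make_poisson_data(200)  # C is pure noise
  sp <- specification(c("A", "B", "C"), include = c("A", "B", "C"))
  f <- repair_spec(d, sp, alpha_sig = 0.1)
  expect_equal(unname(f$spec$alpha), c(1L, 1L, 0L))
  co <- f$coefficients
  expect_true(all(co$p.value[co$role == "coefficient"] <= 0.1))
})

test_that("an insignificant scale demotes the factor to a fixed effect", {
  d <- make_mixed_data(300, seed = 5, omega = 0)  # no real heterogeneity
  sp <- specification(c("A", "C"), include = c("A", "C"), random = "C",
                      distribution = c(C = "normal"))
  f <- repair_spec(d, sp, hdraws = 100)
  expect_equal(unname(f$spec$alpha[["C"]]), 1L)  # fixed effect retained
  expect_equal(unname(f$spec$rand[["C"]]), 0L)   # randomness dropped
})

test_that("repair terminates within the number of estimated terms", {
  set.seed(31)
  n <- 150
  df <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n), D = rnorm(n))
  df$y <- rpois(n, exp(0.3))  # nothing is informative
  d <- count_dataset(df, "y")
  sp <- specification(c("A", "B", "C", "D"), include = c("A", "B", "C", "D"))
  f <- repair_spec(d, sp)
  # everything noise: only the intercept survives
  expect_equal(sum(f$spec$alpha), 0)
  expect_true(f$converged)
})

test_that("forced factors survive repair", {
  d <- make_poisson_data(200)
  space <- search_space(d, prespec = prespecification(include = c(C = 1L)),
                        models = "Poisson", distributions = "normal",
                        transformations = "identity")
  sp <- specification(c("A", "B", "C"), include = c("A", "B", "C"))
  f <- repair_spec(d, sp, space = space)
  expect_equal(unname(f$spec$alpha[["C"]]), 1L)
})
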