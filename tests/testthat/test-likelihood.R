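test_that("pmfs agree with closed forms and the NB cross-checks dnbinom", {
  expect_equal(count_pmf(0, 1, model = "Poisson"), exp(-1))
  expect_equal(count_pmf(0, 1, phi = 1, model = "NB"), 0.5)
  expect_equal(count_pmf(3, 2, phi = 1e-12, model = "GP"), dpois(3, 2),
               tolerance = 1e-9)
  # hand-written NB2 vs the stats implementation
  y <- 0:30
  for (phi in c(0.2, 1, 3)) {
    for (lam in c(0.5, 2, 10)) {
      expect_equal(count_pmf(y, lam, phi, "NB"),
                   dnbinom(y, size = 1 / phi, mu = lam), tolerance = 1e-12)
    }
  }
  expect_error(count_pmf(-1, 1, model = "Poisson"),
               class = "countspec_validation_error")
})

test_that("each pmf normalizes to one over a high truncation point", {
  # the GP tail decay rate is (delta - log(delta) - 1) with
  # delta = phi*lambda / (1 + phi*lambda); keep phi*lambda <= 4 so the
  # truncated sum converges to 1e-8 within the truncation point
  ymax <- 3000
  for (model in cs_model_types()) {
    for (lam in c(0.5, 2, 10)) {
      phis <- if (model == "Poisson") 0 else c(0.1, 0.5, 1.5)
      for (phi in phis[phis * lam <= 4]) {
        s <- sum(count_pmf(0:ymax, lam, phi, model))
        expect_equal(s, 1, tolerance = 1e-8)
      }
    }
  }
})

test_that("NB and GP collapse to Poisson as phi -> 0", {
  y <- 0:50
  for (lam in c(0.5, 2, 8)) {
    p0 <- dpois(y, lam)
    expect_lt(max(abs(count_pmf(y, lam, 1e-8, "NB") - p0)), 1e-6)
    expect_lt(max(abs(count_pmf(y, lam, 1e-8, "GP") - p0)), 1e-6)
  }
})

test_that("the rate equation is exp(linear predictor) with clamping", {
  X <- matrix(c(1, 0), 1)
  expect_equal(drop(rate(X, c(0, 5))), 1)
  expect_equal(drop(rate(matrix(1), log(3))), 3)
  expect_equal(drop(rate(matrix(1), 0, offset = log(2))), 2)
  # monotone in beta_j when X_ij > 0
  lams <- sapply(seq(0, 2, by = 0.5), function(b) drop(rate(matrix(2), b)))
  expect_true(all(diff(lams) > 0))
  expect_equal(drop(rate(matrix(1), 1e4)), 1e10)  # clamp
})

test_that("simulated log-likelihood reduces exactly to the closed form without RPs", {
  d <- make_poisson_data(40)
  sp <- specification(c("A", "B", "C"), include = c("A", "B"))
  des <- build_design(d, sp)
  b <- c(0.4, 0.7, -0.4)
  ll <- simulated_loglik(d, des, sp, list(b = b))
  lam <- drop(exp(des$X %*% b))
  expect_identical(ll, sum(dpois(d$response, lam, log = TRUE)))
})

test_that("a single median draw equals the fixed-effect log-likelihood", {
  d <- make_poisson_data(30)
  sp <- specification(c("A", "B", "C"), include = "A", random = "A",
                      distribution = c(A = "normal"))
  des <- build_design(d, sp)
  dr <- halton_draws(30, 1, 1)
  dr$u[, , 1] <- 0.5
  ll <- simulated_loglik(d, des, sp, list(b = c(0.2, 0.6), omega = 0.5), dr)
  sp0 <- specification(c("A", "B", "C"), include = "A")
  ll0 <- simulated_loglik(d, build_design(d, sp0), sp0, list(b = c(0.2, 0.6)))
  expect_equal(ll, ll0)
})

test_that("simulated log-likelihood is invariant to observation permutation", {
  d <- make_mixed_data(60)
  sp <- specification(c("A", "C"), include = c("A", "C"), random = "C",
                      distribution = c(C = "normal"))
  params <- list(b = c(0.8, 0.6, 0.5), omega = 0.4)
  dr <- halton_draws(60, 50, 1)
  ll1 <- simulated_loglik(d, build_design(d, sp), sp, params, dr)

  perm <- rev(seq_len(60))
  df2 <- data.frame(A = d$factors$A[perm], C = d$factors$C[perm],
                    y = d$response[perm])
  d2 <- count_dataset(df2, "y")
  ll2 <- simulated_loglik(d2, build_design(d2, sp), sp, params, dr)
  # each observation keeps its own draw block, so permuting rows only
  # permutes which block maps to which row; equality holds in expectation
  # and exactly when the draw blocks are also permuted
  dr2 <- dr; dr2$u <- dr$u[perm, , , drop = FALSE]
  ll2p <- simulated_loglik(d2, build_design(d2, sp), sp, params, dr2)
  expect_equal(ll2p, ll1, tolerance = 1e-12)
  expect_lt(abs(ll2 - ll1), 1)  # same draws, reassigned blocks
})

test_that("information criteria match their formulas and zeta counts parameters", {
  expect_equal(information_criterion(-100, 5, 100, "BIC"), 200 + 5 * log(100))
  expect_equal(information_criterion(-100, 5, 100, "AIC"), 210)
  expect_equal(information_criterion(-123.4, 2, 50, "LL"), 123.4)
  expect_error(information_criterion(-1, 1, 0), class = "countspec_validation_error")

  # 3 fixed factors, one of them random: sum(alpha + r) = 4, + intercept
  sp <- specification(paste0("x", 1:4), include = paste0("x", 1:3),
                      random = "x2", model = "Poisson")
  expect_equal(countspec:::spec_zeta(sp), 5)
  sp$model <- "NB"
  expect_equal(countspec:::spec_zeta(sp), 6)  # dispersion adds q = 1
})
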