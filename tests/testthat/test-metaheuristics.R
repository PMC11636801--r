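test_that("pitch adjustment moves toward the mode capped by PAI", {
  expect_equal(pitch_adjust(1, 5, 2), 3)
  expect_equal(pitch_adjust(5, 5, 7), 5)
  expect_equal(pitch_adjust(4, 2, 5), 2)
  expect_equal(pitch_adjust(2, 9, 3), 5)
})

test_that("DE index arithmetic wraps around the ordered decision set", {
  # 0-based: (2 + 1 * (4 - 1)) mod 5 = 0
  expect_equal(de_index(3, 5, 2, 1, 5), 1)
  # zero donor difference leaves the gene unchanged
  expect_equal(de_index(4, 2, 2, 3, 7), 4)
  expect_equal(de_index(1, 2, 1, 2, 3), 3)  # (0 + 2*1) mod 3 = 2 -> index 3
})

test_that("the initial-temperature heuristic realizes the target acceptance", {
  # mean |dE| = 20 at chi = 0.5: T0 = 20 / ln 2
  t0 <- initial_temperature(c(100, 120, 100, 120), 0.5)
  expect_equal(t0, 20 / log(2), tolerance = 1e-10)
  expect_equal(exp(-20 / t0), 0.5, tolerance = 1e-12)
  # chi -> 1 would diverge: capped
  expect_lte(initial_temperature(c(0, 1e9), 1 - 1e-12), 1e8)
  expect_error(initial_temperature(c(Inf, Inf), 0.5),
               class = "countspec_config_error")
})

test_that("search configuration validates its invariants", {
  expect_error(search_config(hmcr = 1.2), "hmcr")
  expect_error(search_config(t_alpha = 1))
  expect_error(search_config(max_time = 0))
  expect_error(differential_evolution(make_poisson_data(20),
                                      make_tiny_space(make_poisson_data(20)),
                                      search_config("DE", ps = 3)),
               class = "countspec_config_error")
})

test_that("evaluation is cached on the canonical chromosome", {
  d <- make_poisson_data(50)
  space <- make_tiny_space(d)
  ctx <- countspec:::make_context(d, space, search_config("SA", hdraws = 30))
  sp <- specification(c("A", "B", "C"), include = "A")
  e1 <- countspec:::evaluate_spec(sp, ctx)
  e2 <- countspec:::evaluate_spec(sp, ctx)
  expect_equal(ctx$evals, 1L)
  expect_equal(ctx$cache_hits, 1L)
  expect_identical(e1$objective, e2$objective)
  # a differently-written but equal model also hits the cache
  sp_b <- specification(c("A", "B", "C"), include = "A",
                        distribution = c(B = "lindley"))
  countspec:::evaluate_spec(sp_b, ctx)
  expect_equal(ctx$cache_hits, 2L)
  # the objective equals the information criterion of the returned fit exactly
  expect_identical(e1$objective,
                   information_criterion(e1$fit$loglik, e1$fit$zeta, d$n, "BIC"))
})

test_that("an infeasible transformation evaluates to +Inf", {
  d <- count_dataset(data.frame(y = rpois(30, 2), A = c(0, rnorm(29))), "y")
  space <- search_space(d, models = "Poisson", distributions = "normal",
                        transformations = c("identity", "ln"),
                        prespec = prespecification(include = c(A = 1L),
                                                   random = c(A = 0L),
                                                   transformation = c(A = "ln")))
  ctx <- countspec:::make_context(d, space, search_config("SA", hdraws = 20))
  ev <- countspec:::evaluate_spec(specification("A", include = "A"), ctx)
  expect_identical(ev$objective, Inf)
})

test_that("each algorithm attains the exhaustive minimum on a tiny space", {
  d <- make_poisson_data(60)
  space <- make_tiny_space(d, models = c("Poisson", "NB"))
  # independent oracle: enumerate and evaluate every specification
  octx <- countspec:::make_context(d, space, search_config("SA", hdraws = 30))
  oracle <- min(vapply(enumerate_space(space, 64),
                       function(s) countspec:::evaluate_spec(s, octx)$objective,
                       numeric(1)))
  cfgs <- list(
    search_config("SA", max_time = 600, max_evals = 40, seed = 2, hdraws = 30,
                  calib_size = 5),
    search_config("HS", max_time = 600, max_evals = 40, seed = 2, hdraws = 30,
                  hms = 8),
    search_config("DE", max_time = 600, max_evals = 40, seed = 2, hdraws = 30,
                  ps = 6))
  for (cfg in cfgs) {
    r <- metaheuristic_search(d, space, cfg)
    expect_equal(r$best_objective, oracle, tolerance = 1e-10)
    # best-so-far is monotone non-increasing
    expect_true(all(diff(r$trajectory$best) <= 1e-12))
    # the returned model is the minimum over everything evaluated
    expect_equal(r$best_objective, min(r$trajectory$incumbent))
  }
})

test_that("searches are reproducible under a fixed seed", {
  d <- make_poisson_data(50)
  space <- make_tiny_space(d)
  cfg <- search_config("SA", max_time = 600, max_evals = 15, seed = 5,
                       hdraws = 20, calib_size = 4)
  r1 <- simulated_annealing(d, space, cfg)
  r2 <- simulated_annealing(d, space, cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(spec_key(r1$best_spec), spec_key(r2$best_spec))
  expect_identical(tidy(r1$best_fit), tidy(r2$best_fit))
})

test_that("zero temperature reduces annealing to strict hill-climbing", {
  d <- make_poisson_data(50)
  space <- make_tiny_space(d)
  cfg <- search_config("SA", max_time = 600, max_evals = 25, seed = 3,
                       hdraws = 20, t0 = 1e-12)
  r <- simulated_annealing(d, space, cfg)
  tr <- r$trajectory[r$trajectory$iteration > 0, ]
  # every accepted move strictly improves (or ties) the incumbent
  expect_true(all(diff(tr$incumbent[tr$accepted] ) <= 1e-9))
})

test_that("initial-plateau acceptance is near chi by construction", {
  d <- make_poisson_data(60)
  space <- make_tiny_space(d, models = c("Poisson", "NB"))
  rates <- vapply(1:3, function(s) {
    cfg <- search_config("SA", max_time = 600, max_evals = 45, seed = s,
                         hdraws = 20, calib_size = 8, t_steps = 30,
                         chi = 0.5)
    r <- simulated_annealing(d, space, cfg)
    tr <- r$trajectory[r$trajectory$iteration > 0, ]
    mean(tr$accepted[seq_len(min(30, nrow(tr)))])
  }, numeric(1))
  expect_gt(mean(rates), 0.5 - 0.15)
})

test_that("harmony memory stays sorted and deduplicated", {
  d <- make_poisson_data(50)
  space <- make_tiny_space(d)
  cfg <- search_config("HS", max_time = 600, max_evals = 30, seed = 11,
                       hdraws = 20, hms = 5)
  r <- harmony_search(d, space, cfg)
  expect_s3_class(r, "count_search")
  expect_true(all(diff(r$trajectory$best) <= 1e-12))
  expect_lte(r$evaluations, 30)
})
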