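make_space <- function(...) {
  d <- count_dataset(data.frame(y = rpois(20, 2), A = rnorm(20),
                                B = rnorm(20), C = rnorm(20)), "y")
  search_space(d, ...)
}

test_that("a random parameter always implies inclusion of its fixed effect", {
  sp <- specification(c("A", "B"), random = "B")
  expect_equal(unname(sp$alpha[["B"]]), 1L)
  set.seed(1)
  space <- make_space()
  for (i in 1:50) {
    s <- random_specification(space)
    expect_true(all(s$alpha >= s$rand))
  }
})

test_that("contradictory pre-specifications are rejected at load", {
  expect_error(prespecification(include = c(A = 0L), random = c(A = 1L)),
               class = "countspec_config_error")
})

test_that("generated specifications honor clamps, sets and the one-model rule", {
  set.seed(42)
  space <- make_space(prespec = prespecification(include = c(A = 1L),
                                                 random = c(B = 0L),
                                                 model = "NB"),
                      distributions = c("normal", "lindley"),
                      transformations = c("ln", "arcsinh"))
  for (i in 1:50) {
    s <- random_specification(space)
    expect_spec_valid(s, space)
    expect_equal(unname(s$alpha[["A"]]), 1L)
    expect_equal(unname(s$rand[["B"]]), 0L)
    expect_identical(s$model, "NB")
    expect_true(all(s$dist[s$rand == 1L] %in% c("normal", "lindley")))
    expect_true(all(s$trans[s$alpha == 1L] %in% c("identity", "ln", "arcsinh")))
  }
  # determinism
  s1 <- random_specification(space, seed = 9)
  s2 <- random_specification(space, seed = 9)
  expect_identical(spec_key(s1), spec_key(s2))
})

test_that("normalization is idempotent and canonicalizes inactive genes", {
  space <- make_space()
  raw <- specification(c("A", "B", "C"), include = "A",
                       transformation = c(A = "sqrt"))
  raw$rand["B"] <- 1L  # violates alpha >= r until normalized
  raw$dist["C"] <- "lindley"   # meaningless: C not random
  raw$trans["C"] <- "cubed"    # meaningless: C not included
  n1 <- normalize_spec(raw, space)
  expect_equal(unname(n1$alpha[["B"]]), 1L)
  expect_identical(unname(n1$dist[["C"]]), "gamma")      # canonical first
  expect_identical(unname(n1$trans[["C"]]), "identity")
  n2 <- normalize_spec(n1, space)
  expect_identical(spec_key(n1), spec_key(n2))
  expect_identical(n1, n2)
})

test_that("equal models share one canonical encoding", {
  space <- make_space()
  a <- specification(c("A", "B", "C"), include = "A")
  b <- specification(c("A", "B", "C"), include = "A",
                     distribution = c(B = "lindley"),
                     transformation = c(C = "exp"))
  expect_identical(spec_key(normalize_spec(a, space)),
                   spec_key(normalize_spec(b, space)))
})

test_that("mutation makes 1 to 3 gene changes and keeps constraints", {
  set.seed(7)
  space <- make_space()
  s <- random_specification(space)
  n_changes <- integer(100)
  for (i in 1:100) {
    m <- mutate_spec(s, space)
    n_changes[i] <- attr(m, "n_mutations")
    expect_spec_valid(m, space)
  }
  expect_true(all(n_changes %in% 1:3))
  expect_setequal(unique(n_changes), 1:3)
  # reproducible neighbor under a fixed seed
  m1 <- mutate_spec(s, space, seed = 4)
  m2 <- mutate_spec(s, space, seed = 4)
  expect_identical(spec_key(m1), spec_key(m2))
})

test_that("enumeration counts follow the product formula and is duplicate-free", {
  space <- make_space(models = "Poisson", distributions = "normal",
                      transformations = "identity",
                      prespec = prespecification(random = c(A = 0L, B = 0L, C = 0L)))
  specs <- enumerate_space(space)
  expect_equal(length(specs), 8)  # 2^3 inclusion patterns
  expect_equal(spec_cardinality(space), 8)

  space2 <- make_space(models = c("Poisson", "NB"), distributions = "normal",
                       transformations = "identity",
                       prespec = prespecification(random = c(A = 0L, B = 0L, C = 0L)))
  specs2 <- enumerate_space(space2)
  expect_equal(length(specs2), 16)
  expect_equal(length(unique(vapply(specs2, spec_key, ""))), 16)

  # unrestricted space: cardinality formula, refusal when over the limit
  space3 <- make_space()
  card <- spec_cardinality(space3)
  per_factor <- 1 + 8 * (1 + 5)  # excluded + trans x (fixed + 5 dists)
  expect_equal(card, per_factor^3 * 3)
  expect_error(enumerate_space(space3, limit = 64), "specifications",
               class = "countspec_config_error")
})

test_that("index round-trips preserve canonical specifications", {
  set.seed(12)
  space <- make_space()
  for (i in 1:25) {
    s <- random_specification(space)
    idx <- countspec:::spec_to_indices(s, space)
    s2 <- normalize_spec(countspec:::indices_to_spec(idx, space), space)
    expect_identical(spec_key(s2), spec_key(s))
  }
})
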