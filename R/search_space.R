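#' Model specification (the chromosome)
#'
#' A specification encodes every decision of the search: per factor `k` an
#' inclusion flag `alpha_k`, a randomness flag `r_k` (random parameters can
#' only be attached to an included factor, `alpha_k >= r_k`), a mixing
#' distribution and a transformation; plus one model type. Genes that are
#' currently meaningless (the distribution of a fixed factor, the
#' transformation of an excluded one) are held at canonical values so that
#' equal models compare equal.
#'
#' @param factors Character vector of all candidate factor names (the factor
#'   universe, order defines the chromosome layout).
#' @param include Names of included factors, or a named 0/1 vector over
#'   `factors`.
#' @param random Names of factors carrying random parameters (subset of
#'   `include`), or a named 0/1 vector.
#' @param distribution Named character vector of mixing distributions for the
#'   random factors (default `"normal"`).
#' @param transformation Named character vector of transformations for
#'   included factors (default `"identity"`).
#' @param model Model type, one of [cs_model_types()].
#' @return Object of class `count_spec`.
#' @examples
#' specification(c("A", "B"), include = "A", model = "Poisson")
#' @export
specification <- function(factors, include = character(), random = character(),
                          distribution = character(), transformation = character(),
                          model = "Poisson") {
  model <- match.arg(model, cs_model_types())
  alpha <- to_flag(include, factors, "include")
  rand <- to_flag(random, factors, "random")
  if (any(rand > alpha)) {
    # a random parameter implies inclusion of the fixed effect
    alpha[rand == 1L] <- 1L
  }
  dist <- setNames(rep(cs_distributions()[1], length(factors)), factors)
  if (length(distribution)) {
    bad <- setdiff(distribution, cs_distributions())
    if (length(bad)) cs_abort(sprintf("unknown distribution(s): %s", paste(bad, collapse = ", ")),
                              "countspec_config_error")
    dist[names(distribution)] <- distribution
  }
  trans <- setNames(rep("identity", length(factors)), factors)
  if (length(transformation)) {
    bad <- setdiff(transformation, cs_transformations())
    if (length(bad)) cs_abort(sprintf("unknown transformation(s): %s", paste(bad, collapse = ", ")),
                              "countspec_config_error")
    trans[names(transformation)] <- transformation
  }
  new_spec(alpha, rand, dist, trans, model)
}

new_spec <- function(alpha, rand, dist, trans, model) {
  structure(list(alpha = alpha, rand = rand, dist = dist, trans = trans,
                 model = model),
            class = "count_spec")
}

to_flag <- function(x, factors, what) {
  if (is.character(x)) {
    bad <- setdiff(x, factors)
    if (length(bad)) cs_abort(sprintf("%s names not in factor universe: %s",
                                      what, paste(bad, collapse = ", ")),
                              "countspec_config_error")
    setNames(as.integer(factors %in% x), factors)
  } else {
    stopifnot(all(names(x) %in% factors))
    out <- setNames(integer(length(factors)), factors)
    out[names(x)] <- as.integer(x)
    out
  }
}

#' @export
print.count_spec <- function(x, ...) {
  inc <- names(x$alpha)[x$alpha == 1L]
  cat(sprintf("<count_spec> %s model, %d/%d factors\n", x$model,
              length(inc), length(x$alpha)))
  for (k in inc) {
    cat(sprintf("  %s [%s]%s\n", k, x$trans[[k]],
                if (x$rand[[k]] == 1L) paste0(" + random(", x$dist[[k]], ")") else ""))
  }
  invisible(x)
}

#' Canonical identity key of a specification
#'
#' Two specifications describing the same model have identical keys once
#' normalized; used for duplicate detection in harmony memory and for the
#' evaluation cache.
#'
#' @param spec A `count_spec`.
#' @export
spec_key <- function(spec) {
  paste(c(spec$alpha, spec$rand,
          ifelse(spec$rand == 1L, spec$dist, "."),
          ifelse(spec$alpha == 1L, spec$trans, "."),
          spec$model), collapse = "|")
}

#' Analyst pre-specification constraints
#'
#' Forced decisions that every specification in the search must honor:
#' forced inclusion/exclusion (`include = 1/0`), forced randomness, forced
#' mixing distribution or transformation per factor, and a forced model type.
#' Forcing exclusion of a factor while forcing it random is contradictory
#' (a random parameter requires its fixed effect) and is rejected at load.
#'
#' @param include Named integer vector of forced `alpha` values (1 or 0).
#' @param random Named integer vector of forced `r` values.
#' @param distribution Named character vector of forced distributions.
#' @param transformation Named character vector of forced transformations.
#' @param model Forced model type, or `NULL`.
#' @return Object of class `cs_prespec`.
#' @export
prespecification <- function(include = integer(), random = integer(),
                             distribution = character(),
                             transformation = character(), model = NULL) {
  contradictory <- intersect(names(include)[include == 0L], names(random)[random == 1L])
  if (length(contradictory)) {
    cs_abort(sprintf("contradictory pre-specification (excluded but forced random): %s",
                     paste(contradictory, collapse = ", ")), "countspec_config_error")
  }
  if (!is.null(model)) model <- match.arg(model, cs_model_types())
  bad <- setdiff(distribution, cs_distributions())
  if (length(bad)) cs_abort(sprintf("unknown forced distribution(s): %s", paste(bad, collapse = ", ")),
                            "countspec_config_error")
  bad <- setdiff(transformation, cs_transformations())
  if (length(bad)) cs_abort(sprintf("unknown forced transformation(s): %s", paste(bad, collapse = ", ")),
                            "countspec_config_error")
  structure(list(include = include, random = random, distribution = distribution,
                 transformation = transformation, model = model),
            class = "cs_prespec")
}

#' The search space of specifications
#'
#' Combines the factor universe of a dataset with analyst pre-specifications
#' and global allow-lists restricting the decision sets. Each decision keeps
#' the fixed listed order of its set, which is what the index arithmetic of
#' the discrete metaheuristics operates on.
#'
#' @param dataset A [count_dataset()].
#' @param prespec A [prespecification()].
#' @param models Allowed model types (order kept).
#' @param distributions Allowed mixing distributions.
#' @param transformations Allowed transformations; `"identity"` is always
#'   admissible and listed first.
#' @param bound Positive bound `c` on transformed values.
#' @return Object of class `cs_space`.
#' @export
search_space <- function(dataset, prespec = prespecification(),
                         models = cs_model_types(),
                         distributions = cs_distributions(),
                         transformations = cs_transformations(),
                         bound = 1e5) {
  stopifnot(inherits(dataset, "count_dataset"))
  models <- intersect(cs_model_types(), models)
  models <- cs_model_types()[cs_model_types() %in% models]
  distributions <- cs_distributions()[cs_distributions() %in% distributions]
  transformations <- unique(c("identity",
                              cs_transformations()[cs_transformations() %in% transformations]))
  if (!length(models)) cs_abort("no admissible model types", "countspec_config_error")
  if (!length(distributions)) cs_abort("no admissible distributions", "countspec_config_error")
  if (!is.null(prespec$model) && !prespec$model %in% models) {
    cs_abort("forced model type not in the admissible set", "countspec_config_error")
  }
  fk <- factor_names(dataset)
  for (nmv in c("include", "random")) {
    bad <- setdiff(names(prespec[[nmv]]), fk)
    if (length(bad)) cs_abort(sprintf("pre-specified %s names unknown: %s", nmv,
                                      paste(bad, collapse = ", ")), "countspec_config_error")
  }
  space <- structure(
    list(factors = fk, prespec = prespec, models = models,
         distributions = distributions, transformations = transformations,
         bound = bound),
    class = "cs_space"
  )
  space$genes <- build_genes(space)
  space
}

# Gene table: one row per chromosome position, with its ordered level set
# (already filtered by pre-specification clamps).
build_genes <- function(space) {
  ps <- space$prespec
  rows <- list()
  for (k in space$factors) {
    a_lv <- if (k %in% names(ps$include)) as.character(ps$include[[k]]) else c("0", "1")
    r_lv <- if (k %in% names(ps$random)) as.character(ps$random[[k]]) else c("0", "1")
    if (identical(a_lv, "0")) r_lv <- "0"
    d_lv <- if (k %in% names(ps$distribution)) ps$distribution[[k]] else space$distributions
    t_lv <- if (k %in% names(ps$transformation)) ps$transformation[[k]] else space$transformations
    rows[[length(rows) + 1L]] <- list(factor = k, gene = "alpha", levels = a_lv)
    rows[[length(rows) + 1L]] <- list(factor = k, gene = "rand", levels = r_lv)
    rows[[length(rows) + 1L]] <- list(factor = k, gene = "dist", levels = d_lv)
    rows[[length(rows) + 1L]] <- list(factor = k, gene = "trans", levels = t_lv)
  }
  m_lv <- if (!is.null(ps$model)) ps$model else space$models
  rows[[length(rows) + 1L]] <- list(factor = NA_character_, gene = "model", levels = m_lv)
  rows
}

#' Normalize a specification to canonical, constraint-satisfying form
#'
#' Enforces the constraint system: a random factor pulls in its fixed effect
#' (`r_k = 1` implies `alpha_k = 1`); all analyst clamps are re-applied (with
#' pre-specification taking precedence, so a factor forced out loses its
#' randomness); and meaningless genes are reset to canonical values (first
#' admissible distribution when `r_k = 0`, identity transformation when
#' `alpha_k = 0`). Idempotent.
#'
#' @param spec A `count_spec`.
#' @param space A [search_space()].
#' @return The canonical `count_spec`.
#' @export
normalize_spec <- function(spec, space) {
  ps <- space$prespec
  alpha <- spec$alpha; rand <- spec$rand; dist <- spec$dist; trans <- spec$trans
  model <- spec$model

  # clamps first: pre-specification wins over everything
  if (length(ps$include)) alpha[names(ps$include)] <- as.integer(ps$include)
  if (length(ps$random)) rand[names(ps$random)] <- as.integer(ps$random)
  # alpha >= r, except a forced exclusion silences the random flag
  forced_out <- names(ps$include)[ps$include == 0L]
  rand[forced_out] <- 0L
  alpha[rand == 1L] <- 1L
  if (length(ps$include)) alpha[names(ps$include)] <- as.integer(ps$include)

  if (length(ps$distribution)) dist[names(ps$distribution)] <- ps$distribution
  if (length(ps$transformation)) trans[names(ps$transformation)] <- ps$transformation
  if (!is.null(ps$model)) model <- ps$model
  if (!model %in% space$models) model <- space$models[1]

  # clamp free genes into the admissible sets
  free_d <- setdiff(space$factors, names(ps$distribution))
  dist[free_d][!dist[free_d] %in% space$distributions] <- space$distributions[1]
  free_t <- setdiff(space$factors, names(ps$transformation))
  trans[free_t][!trans[free_t] %in% space$transformations] <- "identity"

  # canonical values for meaningless genes
  canon_d <- vapply(space$factors, function(k) {
    if (k %in% names(ps$distribution)) ps$distribution[[k]] else space$distributions[1]
  }, character(1))
  dist[rand == 0L] <- canon_d[rand == 0L]
  canon_t <- vapply(space$factors, function(k) {
    if (k %in% names(ps$transformation)) ps$transformation[[k]] else "identity"
  }, character(1))
  trans[alpha == 0L] <- canon_t[alpha == 0L]

  new_spec(alpha, rand, dist, trans, model)
}

# ---- index view used by the discrete metaheuristics -------------------------

spec_to_indices <- function(spec, space) {
  vapply(space$genes, function(g) {
    val <- if (g$gene == "model") spec$model else as.character(spec[[g$gene]][[g$factor]])
    i <- match(val, g$levels)
    if (is.na(i)) 1L else i
  }, integer(1))
}

indices_to_spec <- function(idx, space) {
  alpha <- setNames(integer(length(space$factors)), space$factors)
  rand <- alpha
  dist <- setNames(character(length(space$factors)), space$factors)
  trans <- dist
  model <- space$models[1]
  for (j in seq_along(space$genes)) {
    g <- space$genes[[j]]
    val <- g$levels[[idx[j]]]
    switch(g$gene,
      alpha = alpha[g$factor] <- as.integer(val),
      rand = rand[g$factor] <- as.integer(val),
      dist = dist[g$factor] <- val,
      trans = trans[g$factor] <- val,
      model = model <- val
    )
  }
  new_spec(alpha, rand, dist, trans, model)
}

gene_sizes <- function(space) vapply(space$genes, function(g) length(g$levels), integer(1))

#' Draw a random specification
#'
#' Uniform draws over each free decision; all constraints are satisfied by
#' construction via [normalize_spec()]. Deterministic under a fixed RNG
#' state (`set.seed()` before calling, or pass `seed`).
#'
#' @param space A [search_space()].
#' @param seed Optional integer seed.
#' @return A canonical `count_spec`.
#' @export
random_specification <- function(space, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- gene_sizes(space)
  if (spec_cardinality(space) < 1) cs_abort("over-constrained search space",
                                            "countspec_config_error")
  idx <- vapply(sizes, function(s) sample.int(s, 1L), integer(1))
  normalize_spec(indices_to_spec(idx, space), space)
}

#' Mutate a specification (1 to 3 random gene changes)
#'
#' Draws `m ~ U{1, 2, 3}` and applies `m` distinct single-gene changes, each
#' picking a random mutable chromosome position and reassigning it to a
#' different admissible value — add/remove a factor, toggle randomness, or
#' change a distribution, transformation or the model type. The result is
#' passed through [normalize_spec()].
#'
#' @param spec A `count_spec`.
#' @param space A [search_space()].
#' @param seed Optional integer seed.
#' @return A canonical neighboring `count_spec`.
#' @export
mutate_spec <- function(spec, space, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- normalize_spec(spec, space)
  idx <- spec_to_indices(spec, space)
  sizes <- gene_sizes(space)
  # only genes whose change alters the canonical model are worth mutating:
  # distributions require an active random parameter, transformations an
  # included factor; alpha/randomness/model genes always count
  effective <- vapply(space$genes, function(g) {
    switch(g$gene,
           dist = spec$rand[[g$factor]] == 1L,
           trans = spec$alpha[[g$factor]] == 1L,
           TRUE)
  }, logical(1))
  mutable <- which(sizes > 1L & effective)
  if (!length(mutable)) mutable <- which(sizes > 1L)
  if (!length(mutable)) return(normalize_spec(spec, space))
  m <- min(sample.int(3L, 1L), length(mutable))
  pos <- if (length(mutable) == 1L) mutable else sample(mutable, m)
  for (j in pos) {
    alt <- setdiff(seq_len(sizes[j]), idx[j])
    idx[j] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  }
  out <- normalize_spec(indices_to_spec(idx, space), space)
  attr(out, "n_mutations") <- length(pos)
  out
}

#' Number of distinct feasible (normalized) specifications
#' @param space A [search_space()].
#' @export
spec_cardinality <- function(space) {
  ps <- space$prespec
  per_factor <- vapply(space$factors, function(k) {
    a_forced <- if (k %in% names(ps$include)) ps$include[[k]] else NA_integer_
    r_forced <- if (k %in% names(ps$random)) ps$random[[k]] else NA_integer_
    n_d <- if (k %in% names(ps$distribution)) 1L else length(space$distributions)
    n_t <- if (k %in% names(ps$transformation)) 1L else length(space$transformations)
    excl <- if (identical(a_forced, 1L) || identical(r_forced, 1L)) 0L else 1L
    rand_states <- if (identical(r_forced, 0L)) 0L else n_d
    fixed_states <- if (identical(r_forced, 1L)) 0L else 1L
    incl <- if (identical(a_forced, 0L)) 0L else n_t * (fixed_states + rand_states)
    excl + incl
  }, numeric(1))
  n_m <- if (!is.null(ps$model)) 1L else length(space$models)
  prod(per_factor) * n_m
}

#' Enumerate every feasible specification of a small space
#'
#' Exhaustive, duplicate-free enumeration of all normalized specifications —
#' the oracle the metaheuristics are tested against. Refuses (with the
#' computed cardinality in the error) when the space exceeds `limit`.
#'
#' @param space A [search_space()].
#' @param limit Maximum number of specifications to enumerate.
#' @return List of `count_spec` objects.
#' @export
enumerate_space <- function(space, limit = 10000) {
  card <- spec_cardinality(space)
  if (card > limit) {
    cs_abort(sprintf("space holds %.0f specifications, over the limit %d", card, limit),
             "countspec_config_error")
  }
  ps <- space$prespec
  factor_states <- lapply(space$factors, function(k) {
    a_forced <- if (k %in% names(ps$include)) ps$include[[k]] else NA_integer_
    r_forced <- if (k %in% names(ps$random)) ps$random[[k]] else NA_integer_
    d_lv <- if (k %in% names(ps$distribution)) ps$distribution[[k]] else space$distributions
    t_lv <- if (k %in% names(ps$transformation)) ps$transformation[[k]] else space$transformations
    states <- list()
    if (!identical(a_forced, 1L) && !identical(r_forced, 1L)) {
      states[[length(states) + 1L]] <- list(alpha = 0L, rand = 0L, dist = NA, trans = NA)
    }
    if (!identical(a_forced, 0L)) {
      for (tt in t_lv) {
        if (!identical(r_forced, 1L)) {
          states[[length(states) + 1L]] <- list(alpha = 1L, rand = 0L, dist = NA, trans = tt)
        }
        if (!identical(r_forced, 0L)) {
          for (dd in d_lv) {
            states[[length(states) + 1L]] <- list(alpha = 1L, rand = 1L, dist = dd, trans = tt)
          }
        }
      }
    }
    states
  })
  models <- if (!is.null(ps$model)) ps$model else space$models
  grid <- expand.grid(c(lapply(factor_states, seq_along), list(m = seq_along(models))))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    alpha <- setNames(integer(length(space$factors)), space$factors)
    rand <- alpha
    dist <- setNames(rep(NA_character_, length(space$factors)), space$factors)
    trans <- dist
    for (f in seq_along(space$factors)) {
      st <- factor_states[[f]][[grid[i, f]]]
      alpha[f] <- st$alpha; rand[f] <- st$rand
      dist[f] <- if (is.na(st$dist)) space$distributions[1] else st$dist
      trans[f] <- if (is.na(st$trans)) "identity" else st$trans
    }
    out[[i]] <- normalize_spec(
      new_spec(alpha, rand, dist, trans, models[grid[i, "m"]]), space)
  }
  out
}
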