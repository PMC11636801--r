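#' Search configuration
#'
#' Hyperparameters of the three solution algorithms and the shared stopping
#' rule. Defaults follow the recommended settings from the tuning experiments
#' behind the package: simulated annealing with `t_alpha = 0.975` and
#' `t_steps = 5`; harmony search with `hms = 20`, `hmcr = 0.8`, `par = 0.5`;
#' differential evolution with `ps = 20`, `cr = 0.6`; pitch-adjustment index
#' `pai = 2` for HS and DE.
#'
#' The stop rule is wall-clock (`max_time` seconds, checked between
#' evaluations so an in-flight fit completes) and/or an evaluation budget
#' (`max_evals`) for bit-reproducible runs.
#'
#' @param algorithm `"SA"`, `"HS"` or `"DE"`.
#' @param objective `"BIC"` (default), `"AIC"` or `"LL"`.
#' @param max_time Wall-clock budget in seconds.
#' @param max_evals Evaluation budget (default `Inf`).
#' @param seed Master seed; all randomness in the run derives from it.
#' @param hms,hmcr,par,pai Harmony search: memory size, memory consideration
#'   rate, pitch-adjustment rate, pitch-adjustment index (`pai` is shared
#'   with DE).
#' @param chi,t_alpha,t_steps,calib_size Simulated annealing: initial
#'   acceptance level for the temperature heuristic, cooling factor,
#'   steps per temperature, and the size of the seeded random population used
#'   to calibrate the initial temperature.
#' @param t0 Optional fixed initial temperature (skips calibration).
#' @param ps,cr Differential evolution: population size and crossover rate.
#' @param de_pai Index shift used in DE's donor-difference arithmetic. Kept
#'   separate from `pai` with default 1: the modulo update
#'   `(l + de_pai * (l' - l'')) mod |L|` cannot move a two-level gene when
#'   the shift is even, so DE would freeze on binary decisions with the
#'   harmony-search default of 2 (harmony search itself caps the shift with
#'   a minimum, which has no such degeneracy).
#' @param alpha_sig Significance level used by the repair step.
#' @param hdraws Halton draws per observation for simulated likelihood.
#' @param classic_par Use the classical harmony-search trigger (adjust when
#'   the uniform draw is `< par`) instead of the `>= par` direction.
#' @param drop_all Repair drops all insignificant terms per pass.
#' @export
search_config <- function(algorithm = c("SA", "HS", "DE"), objective = "BIC",
                          max_time = 60, max_evals = Inf, seed = 1,
                          hms = 20, hmcr = 0.8, par = 0.5, pai = 2,
                          chi = 0.5, t_alpha = 0.975, t_steps = 5,
                          calib_size = 20, t0 = NULL,
                          ps = 20, cr = 0.6, de_pai = 1,
                          alpha_sig = 0.1, hdraws = 200,
                          classic_par = FALSE, drop_all = FALSE) {
  algorithm <- match.arg(algorithm)
  objective <- match.arg(objective, c("BIC", "AIC", "LL"))
  stopifnot(hmcr > 0, hmcr < 1, par > 0, par < 1, cr > 0, cr <= 1,
            t_alpha > 0, t_alpha < 1, t_steps >= 1, pai >= 1,
            max_time > 0, hms >= 1, ps >= 1, chi > 0, chi < 1,
            de_pai >= 1, alpha_sig > 0, alpha_sig < 1, calib_size >= 2)
  structure(list(algorithm = algorithm, objective = objective,
                 max_time = max_time, max_evals = max_evals, seed = seed,
                 hms = hms, hmcr = hmcr, par = par, pai = pai, chi = chi,
                 t_alpha = t_alpha, t_steps = t_steps, calib_size = calib_size,
                 t0 = t0, ps = ps, cr = cr, de_pai = de_pai,
                 alpha_sig = alpha_sig,
                 hdraws = hdraws, classic_par = classic_par,
                 drop_all = drop_all),
            class = "cs_config")
}

#' Pitch adjustment of a decision index
#'
#' Shifts the current index toward the modal index of the harmony memory for
#' that gene, moving by the smaller of the index difference and the
#' pitch-adjustment index `pai`.
#'
#' @param current Current index.
#' @param mode Modal index in harmony memory.
#' @param pai Pitch-adjustment index (maximum allowed movement).
#' @return The adjusted index.
#' @examples
#' pitch_adjust(1, 5, 2)  # 3
#' pitch_adjust(4, 2, 5)  # 2
#' @export
pitch_adjust <- function(current, mode, pai) {
  current + sign(mode - current) * min(abs(mode - current), pai)
}

#' Initial temperature heuristic for simulated annealing
#'
#' `T0 = mean(|dE|) / (-log(chi))`, where `mean(|dE|)` is the mean absolute
#' objective difference between successive random solutions. By construction
#' the Metropolis acceptance probability of an average-sized uphill move at
#' the start equals `chi`.
#'
#' @param sample_objectives Objective values of a random initial population.
#' @param chi Target initial acceptance probability, in (0, 1).
#' @return Positive initial temperature (capped at 1e8).
#' @examples
#' initial_temperature(c(100, 120, 80), 0.5)  # mean|dE| = 30 -> 30/log(2)
#' @export
initial_temperature <- function(sample_objectives, chi = 0.5) {
  e <- sample_objectives[is.finite(sample_objectives)]
  if (length(e) < 2) {
    cs_abort("need at least two finite objectives to calibrate T0; use a larger calibration population",
             "countspec_config_error")
  }
  de <- mean(abs(diff(e)))
  if (de == 0) de <- 1
  min(de / (-log(chi)), 1e8)
}

# ---- evaluation context -----------------------------------------------------

# Mutable state shared by one search run: dataset, space, draw set, cache of
# repaired fits keyed on canonical chromosomes, counters, trajectory.
make_context <- function(dataset, space, config, control = fit_control()) {
  ctx <- new.env(parent = emptyenv())
  ctx$dataset <- dataset
  ctx$space <- space
  ctx$config <- config
  control$se <- "opg"  # fast intermediate SEs; the final model is re-fit
  ctx$control <- control
  ctx$report_control <- control; ctx$report_control$se <- "hessian"
  ctx$draws <- halton_draws(dataset$n, config$hdraws,
                            n_dims = max(1L, length(space$factors)))
  ctx$cache <- new.env(parent = emptyenv())
  ctx$evals <- 0L
  ctx$cache_hits <- 0L
  ctx$t_start <- proc.time()[["elapsed"]]
  ctx$traj <- list()
  ctx$best_obj <- Inf
  ctx$best_fit <- NULL
  ctx
}

stop_now <- function(ctx) {
  # the evaluation budget counts proposals, cached or not; otherwise a small
  # fully-cached space could never exhaust it
  (proc.time()[["elapsed"]] - ctx$t_start) >= ctx$config$max_time ||
    (ctx$evals + ctx$cache_hits) >= ctx$config$max_evals
}

# normalize -> cache -> fit -> repair -> objective; the repaired chromosome is
# what the caller embeds back into its population/memory.
evaluate_spec <- function(spec, ctx, start = NULL) {
  spec <- normalize_spec(spec, ctx$space)
  key <- spec_key(spec)
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) {
    ctx$cache_hits <- ctx$cache_hits + 1L
    return(hit)
  }
  cfg <- ctx$config
  ctrl <- ctx$control
  if (!is.null(start)) ctrl$start <- start
  fit <- repair_spec(ctx$dataset, spec, draws = ctx$draws,
                     alpha_sig = cfg$alpha_sig, drop_all = cfg$drop_all,
                     space = ctx$space, hdraws = cfg$hdraws,
                     bound = ctx$space$bound, objective = cfg$objective,
                     control = ctrl)
  obj <- if (fit$converged) fit$objective else Inf
  out <- list(objective = obj, fit = fit,
              spec = normalize_spec(fit$spec, ctx$space))
  out$key <- spec_key(out$spec)
  ctx$evals <- ctx$evals + 1L
  ctx$cache[[key]] <- out
  ctx$cache[[out$key]] <- out
  if (obj < ctx$best_obj) {
    ctx$best_obj <- obj
    ctx$best_fit <- fit
  }
  out
}

log_step <- function(ctx, iteration, incumbent, accepted) {
  ctx$traj[[length(ctx$traj) + 1L]] <-
    list(iteration = iteration, incumbent = incumbent, best = ctx$best_obj,
         accepted = accepted)
}

# scales / dispersion of a converged fit, reusable as a warm start for a
# neighboring specification
warm_start_from <- function(fit) {
  if (is.null(fit) || !isTRUE(fit$converged)) return(NULL)
  co <- fit$coefficients
  list(omega = setNames(co$estimate[co$role == "scale"],
                        co$factor[co$role == "scale"]),
       phi = if (any(co$role == "dispersion")) co$estimate[co$role == "dispersion"])
}

finish_search <- function(ctx, algorithm) {
  traj <- dplyr::bind_rows(lapply(ctx$traj, tibble::as_tibble))
  # report the best model with Hessian-based standard errors
  if (!is.null(ctx$best_fit) && isTRUE(ctx$best_fit$converged)) {
    cfg <- ctx$config
    refit <- repair_spec(ctx$dataset, ctx$best_fit$spec, draws = ctx$draws,
                         alpha_sig = cfg$alpha_sig, drop_all = cfg$drop_all,
                         space = ctx$space, hdraws = cfg$hdraws,
                         bound = ctx$space$bound, objective = cfg$objective,
                         control = ctx$report_control)
    if (isTRUE(refit$converged) && refit$objective <= ctx$best_obj + 1e-9) {
      ctx$best_fit <- refit
      ctx$best_obj <- min(ctx$best_obj, refit$objective)
    }
  }
  structure(
    list(best_fit = ctx$best_fit,
         best_spec = if (!is.null(ctx$best_fit)) ctx$best_fit$spec else NULL,
         best_objective = ctx$best_obj, trajectory = traj,
         evaluations = ctx$evals, cache_hits = ctx$cache_hits,
         wall_time = proc.time()[["elapsed"]] - ctx$t_start,
         algorithm = algorithm, config = ctx$config),
    class = "count_search")
}

#' @export
print.count_search <- function(x, ...) {
  cat(sprintf("<count_search> %s: best %s = %.4f after %d evaluations (%.1fs, %d cache hits)\n",
              x$algorithm, x$config$objective, x$best_objective,
              x$evaluations, x$wall_time, x$cache_hits))
  if (!is.null(x$best_fit)) print(x$best_fit)
  invisible(x)
}

init_population <- function(n, space, initial = NULL) {
  pop <- list()
  if (!is.null(initial)) {
    if (inherits(initial, "count_spec")) initial <- list(initial)
    pop <- lapply(initial, normalize_spec, space = space)
  }
  while (length(pop) < n) {
    pop[[length(pop) + 1L]] <- random_specification(space)
  }
  pop[seq_len(n)]
}

# ---- harmony search ---------------------------------------------------------

#' Discrete Harmony Search over model specifications
#'
#' Maintains a harmony memory of `hms` elite (repaired) specifications sorted
#' by objective. Each iteration builds a candidate gene-wise: with
#' probability `hmcr` a gene is copied from a random memory member, otherwise
#' drawn at random; then, if a uniform draw is `>= par` (or `< par` with
#' `classic_par = TRUE`), every gene is pitch-adjusted toward the memory's
#' modal index by at most `pai` positions. The candidate is repaired and, if
#' better than the worst member (and not already in memory), replaces it.
#'
#' @param dataset A [count_dataset()].
#' @param space A [search_space()].
#' @param config A [search_config()].
#' @param initial Optional initial specification(s) seeded into memory.
#' @param control A [fit_control()].
#' @return A `count_search` result.
#' @export
harmony_search <- function(dataset, space, config = search_config("HS"),
                           initial = NULL, control = fit_control()) {
  set.seed(config$seed)
  ctx <- make_context(dataset, space, config, control)
  sizes <- gene_sizes(space)
  n_genes <- length(sizes)

  pop <- init_population(config$hms, space, initial)
  hm <- list()
  for (i in seq_along(pop)) {
    ev <- evaluate_spec(pop[[i]], ctx)
    log_step(ctx, 0L, ev$objective, TRUE)
    if (!ev$key %in% vapply(hm, `[[`, "", "key")) hm[[length(hm) + 1L]] <- ev
    if (stop_now(ctx)) break
  }
  sort_hm <- function(hm) hm[order(vapply(hm, `[[`, 0, "objective"))]
  hm <- sort_hm(hm)

  iter <- 0L
  while (!stop_now(ctx)) {
    iter <- iter + 1L
    hm_idx <- vapply(hm, function(m) spec_to_indices(m$spec, space), integer(n_genes))
    if (is.null(dim(hm_idx))) hm_idx <- matrix(hm_idx, nrow = n_genes)
    cand <- integer(n_genes)
    for (j in seq_len(n_genes)) {
      if (runif(1) <= config$hmcr) {
        cand[j] <- hm_idx[j, sample.int(ncol(hm_idx), 1L)]
      } else {
        cand[j] <- sample.int(sizes[j], 1L)
      }
    }
    u <- runif(1)
    adjust <- if (config$classic_par) u < config$par else u >= config$par
    if (adjust) {
      for (j in seq_len(n_genes)) {
        tab <- tabulate(hm_idx[j, ], nbins = sizes[j])
        mode_j <- which.max(tab)
        cand[j] <- pitch_adjust(cand[j], mode_j, config$pai)
      }
    }
    ev <- evaluate_spec(indices_to_spec(cand, space), ctx)
    worst <- hm[[length(hm)]]$objective
    accepted <- ev$objective < worst &&
      !ev$key %in% vapply(hm, `[[`, "", "key")
    if (accepted) {
      hm[[length(hm)]] <- ev
      hm <- sort_hm(hm)
    }
    log_step(ctx, iter, ev$objective, accepted)
  }
  finish_search(ctx, "HS")
}

# ---- simulated annealing ----------------------------------------------------

#' Simulated Annealing over model specifications
#'
#' Calibrates the initial temperature with [initial_temperature()] on a
#' seeded random population, then repeatedly proposes neighbors via
#' [mutate_spec()] (1–3 gene changes). A proposal is accepted if it improves
#' the objective, or with Metropolis probability `exp(-dE / T)` otherwise;
#' after `t_steps` proposals the temperature cools by the factor `t_alpha`.
#' Incumbent and best-so-far are tracked separately in the trajectory.
#'
#' @inheritParams harmony_search
#' @return A `count_search` result.
#' @export
simulated_annealing <- function(dataset, space, config = search_config("SA"),
                                initial = NULL, control = fit_control()) {
  set.seed(config$seed)
  ctx <- make_context(dataset, space, config, control)

  start <- init_population(1L, space, initial)[[1]]
  cur <- evaluate_spec(start, ctx)
  log_step(ctx, 0L, cur$objective, TRUE)

  if (is.null(config$t0)) {
    # keep drawing until enough *finite* objectives: random specifications may
    # legitimately be infeasible (rejected transformations)
    calib <- numeric(0)
    attempts <- 0L
    while (sum(is.finite(calib)) < config$calib_size &&
           attempts < 10L * config$calib_size && !stop_now(ctx)) {
      attempts <- attempts + 1L
      ev <- evaluate_spec(random_specification(space), ctx)
      log_step(ctx, 0L, ev$objective, FALSE)
      calib <- c(calib, ev$objective)
    }
    temp <- initial_temperature(c(cur$objective, calib), config$chi)
  } else {
    temp <- config$t0
  }

  iter <- 0L
  while (!stop_now(ctx)) {
    for (s in seq_len(config$t_steps)) {
      if (stop_now(ctx)) break
      iter <- iter + 1L
      nb <- mutate_spec(cur$spec, space)
      ev <- evaluate_spec(nb, ctx, start = warm_start_from(cur$fit))
      de <- ev$objective - cur$objective
      accepted <- if (!is.finite(cur$objective)) {
        # infeasible incumbent: any move that is no worse keeps the chain
        # mobile (equal-energy moves across the infeasible plateau included)
        TRUE
      } else {
        is.finite(ev$objective) &&
          (de <= 0 || (temp > 0 && runif(1) < exp(-de / temp)))
      }
      if (accepted) cur <- ev
      log_step(ctx, iter, cur$objective, accepted)
    }
    temp <- max(temp * config$t_alpha, 1e-12)
  }
  finish_search(ctx, "SA")
}

# ---- differential evolution -------------------------------------------------

#' Discrete Differential Evolution over model specifications
#'
#' For each population member `p`, two distinct random members `p'` and `p''`
#' are picked and a trial is built gene-wise: with probability `cr` the index
#' becomes `(l_p + pai * (l_p' - l_p'')) mod |L_j|` over the gene's ordered
#' decision set, otherwise the gene is kept. The trial is repaired and
#' replaces `p` when better.
#'
#' @inheritParams harmony_search
#' @return A `count_search` result.
#' @export
differential_evolution <- function(dataset, space, config = search_config("DE"),
                                   initial = NULL, control = fit_control()) {
  if (config$ps < 4) cs_abort("differential evolution needs a population of at least 4",
                              "countspec_config_error")
  set.seed(config$seed)
  ctx <- make_context(dataset, space, config, control)
  sizes <- gene_sizes(space)
  n_genes <- length(sizes)

  pop <- init_population(config$ps, space, initial)
  members <- vector("list", config$ps)
  for (i in seq_along(pop)) {
    members[[i]] <- evaluate_spec(pop[[i]], ctx)
    log_step(ctx, 0L, members[[i]]$objective, TRUE)
    if (stop_now(ctx)) break
  }
  if (any(vapply(members, is.null, TRUE))) return(finish_search(ctx, "DE"))

  iter <- 0L
  while (!stop_now(ctx)) {
    for (p in seq_len(config$ps)) {
      if (stop_now(ctx)) break
      iter <- iter + 1L
      others <- sample(setdiff(seq_len(config$ps), p), 2L)
      l_p <- spec_to_indices(members[[p]]$spec, space)
      l_p1 <- spec_to_indices(members[[others[1]]]$spec, space)
      l_p2 <- spec_to_indices(members[[others[2]]]$spec, space)
      trial <- l_p
      for (j in seq_len(n_genes)) {
        if (runif(1) <= config$cr) {
          trial[j] <- de_index(l_p[j], l_p1[j], l_p2[j], config$de_pai, sizes[j])
        }
      }
      ev <- evaluate_spec(indices_to_spec(trial, space), ctx)
      accepted <- ev$objective < members[[p]]$objective
      if (accepted) members[[p]] <- ev
      log_step(ctx, iter, ev$objective, accepted)
    }
  }
  finish_search(ctx, "DE")
}

#' Differential-evolution index arithmetic
#'
#' The discrete mutation `(l_p + pai * (l_p' - l_p'')) mod set_size` on a
#' gene's ordered decision set (0-based arithmetic on 1-based indices).
#'
#' @param l_p,l_p1,l_p2 Indices of the target and the two donor solutions.
#' @param pai Pitch-adjustment index amplifying the donor difference.
#' @param set_size Size of the ordered decision set.
#' @return The trial index (1-based).
#' @examples
#' de_index(3, 5, 2, 1, 5)  # (2 + (4 - 1)) mod 5 -> index 1 (0-based 0)
#' @export
de_index <- function(l_p, l_p1, l_p2, pai, set_size) {
  (((l_p - 1L) + pai * (l_p1 - l_p2)) %% set_size) + 1L
}

#' Run the configured metaheuristic
#'
#' Dispatches to [harmony_search()], [simulated_annealing()] or
#' [differential_evolution()] per `config$algorithm`.
#'
#' @inheritParams harmony_search
#' @export
metaheuristic_search <- function(dataset, space, config, initial = NULL,
                                 control = fit_control()) {
  switch(config$algorithm,
         HS = harmony_search(dataset, space, config, initial, control),
         SA = simulated_annealing(dataset, space, config, initial, control),
         DE = differential_evolution(dataset, space, config, initial, control))
}
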