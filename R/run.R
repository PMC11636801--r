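#' Assemble a reproducible run configuration
#'
#' Everything a search run needs, fully serializable: data options, search
#' space restrictions and pre-specifications, the metaheuristic
#' configuration, an optional initial solution, and the output directory.
#' A run is reproducible from its archived configuration plus the seed.
#'
#' @param data_path Path to the delimited data table (ignored when `dataset`
#'   is supplied directly to [run_search()]).
#' @param response Response column name.
#' @param offset Optional offset column name.
#' @param out_dir Output directory for artifacts (`NULL` = write nothing).
#' @param algorithm,objective,max_time,max_evals,seed,hdraws Passed to
#'   [search_config()], together with `...`.
#' @param models,distributions,transformations,bound Passed to
#'   [search_space()].
#' @param prespec A [prespecification()], or a list with elements `include`,
#'   `random`, `distribution`, `transformation`, `model`.
#' @param initial Optional initial solution: a `count_spec`, or the
#'   serialized form accepted by [read_spec()].
#' @param ... Further [search_config()] arguments.
#' @return Object of class `cs_runconfig`.
#' @export
run_config <- function(data_path = NULL, response = "Y", offset = NULL,
                       out_dir = NULL, algorithm = "SA", objective = "BIC",
                       max_time = 60, max_evals = Inf, seed = 1, hdraws = 200,
                       models = cs_model_types(),
                       distributions = cs_distributions(),
                       transformations = cs_transformations(),
                       bound = 1e5, prespec = NULL, initial = NULL, ...) {
  if (is.list(prespec) && !inherits(prespec, "cs_prespec")) {
    prespec <- do.call(prespecification, prespec)
  }
  cfg <- search_config(algorithm = algorithm, objective = objective,
                       max_time = max_time, max_evals = max_evals,
                       seed = seed, hdraws = hdraws, ...)
  structure(list(data_path = data_path, response = response, offset = offset,
                 out_dir = out_dir, search = cfg, models = models,
                 distributions = distributions,
                 transformations = transformations, bound = bound,
                 prespec = prespec %||% prespecification(),
                 initial = initial),
            class = "cs_runconfig")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]: `data_path`,
#' `response`, `offset`, `out_dir`, `algorithm`, `objective`, `max_time`,
#' `max_evals`, `seed`, `hdraws`, `models`, `distributions`,
#' `transformations`, `bound`, nested `prespec` (with `include`, `random`,
#' `distribution`, `transformation`, `model`) and a nested `initial`
#' specification in the [write_spec()] schema, plus any [search_config()]
#' hyperparameter (`hms`, `hmcr`, `par`, `pai`, `chi`, `t_alpha`, `t_steps`,
#' `ps`, `cr`, `alpha_sig`, ...).
#'
#' @param path YAML file path.
#' @return A `cs_runconfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) cs_abort(sprintf("config file not found: %s", path),
                                   "countspec_config_error")
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$prespec)) {
    pp <- obj$prespec
    obj$prespec <- prespecification(
      include = unlist(pp$include) %||% integer(),
      random = unlist(pp$random) %||% integer(),
      distribution = unlist(pp$distribution) %||% character(),
      transformation = unlist(pp$transformation) %||% character(),
      model = pp$model)
  }
  if (!is.null(obj$initial)) obj$initial <- read_spec(obj$initial)
  do.call(run_config, obj)
}

serialize_run_config <- function(config) {
  out <- list(data_path = config$data_path, response = config$response,
              offset = config$offset, out_dir = config$out_dir,
              models = config$models, distributions = config$distributions,
              transformations = config$transformations, bound = config$bound)
  out <- c(out, unclass(config$search))
  ps <- config$prespec
  if (length(ps$include) || length(ps$random) || length(ps$distribution) ||
      length(ps$transformation) || !is.null(ps$model)) {
    out$prespec <- list(include = as.list(ps$include),
                        random = as.list(ps$random),
                        distribution = as.list(ps$distribution),
                        transformation = as.list(ps$transformation),
                        model = ps$model)
  }
  if (!is.null(config$initial)) {
    init <- config$initial
    out$initial <- if (inherits(init, "count_spec")) write_spec(init) else init
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Run a full specification search
#'
#' The end-to-end analyst workflow: load the data (unless a dataset is
#' passed), build the constrained search space, run the configured
#' metaheuristic, and (when `out_dir` is set) write four artifacts —
#' `best_model.txt` (the coefficient table), `best_spec.yml` (the best
#' specification, re-loadable as an initial solution), `trajectory.csv`
#' (per-iteration incumbent/best objectives) and `run.yml` + `run_log.txt`
#' (the archived configuration; seed, evaluation count, wall time).
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @param dataset Optional [count_dataset()] overriding `config$data_path`.
#' @return A `count_search` result (invisibly when artifacts are written).
#' @export
run_search <- function(config, dataset = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "cs_runconfig"))
  if (is.null(dataset)) {
    if (is.null(config$data_path)) cs_abort("no dataset and no data_path in config",
                                            "countspec_config_error")
    dataset <- load_dataset(config$data_path, config$response, config$offset)
  }
  space <- search_space(dataset, prespec = config$prespec,
                        models = config$models,
                        distributions = config$distributions,
                        transformations = config$transformations,
                        bound = config$bound)
  initial <- config$initial
  if (!is.null(initial) && !inherits(initial, "count_spec")) {
    initial <- read_spec(initial)
  }
  result <- metaheuristic_search(dataset, space, config$search,
                                 initial = initial,
                                 control = fit_control(seed = config$search$seed))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    render_report(result$best_fit, file.path(od, "best_model.txt"))
    write_spec(result$best_spec, file.path(od, "best_spec.yml"))
    readr::write_csv(result$trajectory, file.path(od, "trajectory.csv"))
    yaml::write_yaml(serialize_run_config(config), file.path(od, "run.yml"))
    writeLines(c(
      sprintf("algorithm: %s", result$algorithm),
      sprintf("seed: %s", config$search$seed),
      sprintf("evaluations: %d", result$evaluations),
      sprintf("cache_hits: %d", result$cache_hits),
      sprintf("wall_time_s: %.2f", result$wall_time),
      sprintf("best_%s: %.6f", config$search$objective, result$best_objective)
    ), file.path(od, "run_log.txt"))
    return(invisible(result))
  }
  result
}
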