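sig_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

trans_label <- function(t) ifelse(is.na(t) | t == "identity", "no", t)

#' Render a fitted model as a coefficient table
#'
#' Produces the standard reporting layout: a main block with Effect, the
#' applied transformation ("no" for identity), coefficient, standard error,
#' z-value and two-sided p-value with significance stars (*** p<0.01,
#' ** p<0.05, * p<0.1); a separate "Scale Parameters for Distributions of
#' Random Parameters" block naming each distribution; and a footer with the
#' dispersion coefficient (when present), model type, log-likelihood and BIC.
#'
#' @param fit A `count_fit`.
#' @param file Optional path; the text table is written there.
#' @return Invisibly, a character vector of table lines. The tabular data
#'   itself is available via [tidy.count_fit()].
#' @export
render_report <- function(fit, file = NULL) {
  stopifnot(inherits(fit, "count_fit"))
  co <- fit$coefficients
  fmt <- function(v) formatC(v, digits = 2, format = "f")
  main <- co[co$role %in% c("intercept", "coefficient"), , drop = FALSE]
  scales <- co[co$role == "scale", , drop = FALSE]
  disp <- co[co$role == "dispersion", , drop = FALSE]

  row_line <- function(effect, tau, est, se, z, p) {
    sprintf("%-28s %-10s %10s %10s %8s %8s%s",
            effect, tau, fmt(est), fmt(se), fmt(z), fmt(p), sig_stars(p))
  }
  lines <- c(
    sprintf("%-28s %-10s %10s %10s %8s %8s", "Effect", "tau", "Coeff",
            "Std.Err", "z", "Prob|z|>Z"),
    vapply(seq_len(nrow(main)), function(i) {
      row_line(main$term[i], trans_label(main$transformation[i]),
               main$estimate[i], main$std.error[i], main$statistic[i],
               main$p.value[i])
    }, character(1))
  )
  lines <- c(lines, "Scale Parameters for Distributions of Random Parameters")
  if (nrow(scales)) {
    lines <- c(lines, vapply(seq_len(nrow(scales)), function(i) {
      row_line(sprintf("%s (Std. Dev.) %s", scales$factor[i], scales$distribution[i]),
               trans_label(scales$transformation[i]),
               scales$estimate[i], scales$std.error[i], scales$statistic[i],
               scales$p.value[i])
    }, character(1)))
  } else {
    lines <- c(lines, "  (none)")
  }
  if (nrow(disp)) {
    lines <- c(lines, sprintf("Dispersion Coeff %s", fmt(disp$estimate[1])))
  }
  lines <- c(lines,
             sprintf("Model Type %s", fit$model),
             sprintf("Log-Likelihood %.2f", fit$loglik),
             sprintf("BIC %.2f", fit$bic %||% fit$objective),
             "***p<0.01; **p<0.05; *p<0.1")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Serialize a specification to a YAML-ready list / file
#'
#' The archived form of a specification, re-loadable as an initial solution:
#' included factors with their transformations, random factors with their
#' distributions, and the model type.
#'
#' @param spec A `count_spec`.
#' @param file Optional path to write YAML to.
#' @return Invisibly, the serializable list.
#' @export
write_spec <- function(spec, file = NULL) {
  inc <- names(spec$alpha)[spec$alpha == 1L]
  rnd <- names(spec$rand)[spec$rand == 1L]
  out <- list(
    factors = names(spec$alpha),
    include = as.list(setNames(spec$trans[inc], inc)),
    random = as.list(setNames(spec$dist[rnd], rnd)),
    model = spec$model
  )
  if (!is.null(file)) yaml::write_yaml(out, file)
  invisible(out)
}

#' Read a specification from its serialized form
#'
#' @param x A YAML file path or the list produced by [write_spec()].
#' @return A `count_spec`.
#' @export
read_spec <- function(x) {
  obj <- if (is.character(x)) yaml::read_yaml(x) else x
  inc <- names(obj$include) %||% character(0)
  rnd <- names(obj$random) %||% character(0)
  specification(obj$factors,
                include = inc,
                random = rnd,
                distribution = unlist(obj$random) %||% character(0),
                transformation = unlist(obj$include) %||% character(0),
                model = obj$model %||% "Poisson")
}
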