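#' Convergence plot of a search run
#'
#' Fitness (objective, usually BIC) against iteration: the incumbent
#' solution as points, the best-so-far as a step line — the standard way to
#' read how a metaheuristic explored before stabilizing.
#'
#' @param object A `count_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot count_search
#' @export
autoplot.count_search <- function(object, ...) {
  traj <- object$trajectory
  traj <- traj[is.finite(traj$incumbent), , drop = FALSE]
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$incumbent), alpha = 0.35, size = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best), linewidth = 0.7) +
    ggplot2::labs(x = "Iteration",
                  y = sprintf("Fitness (%s)", object$config$objective),
                  title = sprintf("%s convergence", object$algorithm)) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a fitted model
#'
#' Estimates with approximate 95% intervals (estimate +/- 1.96 SE), faceted
#' into coefficients and random-parameter scales.
#'
#' @param object A `count_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot count_fit
#' @export
autoplot.count_fit <- function(object, ...) {
  co <- object$coefficients
  co <- co[co$role %in% c("intercept", "coefficient", "scale"), , drop = FALSE]
  co$block <- ifelse(co$role == "scale", "Scale parameters", "Coefficients")
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                                         xmax = .data$estimate + 1.96 * .data$std.error),
                            height = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$block), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "Estimate", y = NULL,
                  title = sprintf("%s model (lnL = %.2f, BIC = %.2f)",
                                  object$model, object$loglik,
                                  object$bic %||% NA_real_)) +
    ggplot2::theme_minimal()
}

#' Convergence plot helper
#'
#' Convenience wrapper: `plot_convergence(x)` is `autoplot(x)` for a
#' `count_search`.
#'
#' @param x A `count_search`.
#' @export
plot_convergence <- function(x) autoplot.count_search(x)
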