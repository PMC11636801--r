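#' Transformation decision set
#'
#' The variable transformations the search may apply to a contributing factor,
#' with `"identity"` (reported as "no" in coefficient tables) always first so
#' it is the canonical value for excluded factors. `"factorial"` is evaluated
#' as the gamma function of `x + 1` so non-integer covariates are admissible,
#' with domain restricted to `x >= 0`.
#'
#' @return Character vector of transformation names.
#' @export
cs_transformations <- function() {
  c("identity", "ln", "sqrt", "exp", "squared", "cubed", "factorial", "arcsinh")
}

#' Apply a variable transformation under the boundedness constraint
#'
#' Transforms a factor column and enforces feasibility: the transformation's
#' domain must be respected (`ln` requires all values strictly positive,
#' `sqrt` and `factorial` require non-negative values) and every transformed
#' value must be finite and inside `[-bound, bound]`. An infeasible
#' transformation is a normal outcome of the search, not an error: a rejection
#' object naming the violated rule is returned so the caller can mark the
#' specification infeasible.
#'
#' @param x Numeric vector (a raw factor column).
#' @param tau Transformation name, one of [cs_transformations()].
#' @param bound Positive scalar `c` bounding the transformed values.
#' @return The transformed numeric vector, or an object of class
#'   `cs_rejection` with fields `rule` and `message`.
#' @examples
#' apply_transformation(c(1, exp(1), exp(2)), "ln")
#' apply_transformation(c(-1, 2), "ln")   # rejection: domain
#' @export
apply_transformation <- function(x, tau, bound = 1e5) {
  if (length(tau) != 1L || !tau %in% cs_transformations()) {
    cs_abort(sprintf("unknown transformation '%s'", paste(tau, collapse = ",")),
             "countspec_config_error")
  }
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0) {
    cs_abort("bound must be a positive scalar", "countspec_config_error")
  }
  if (any(!is.finite(x))) {
    return(cs_rejection("domain", sprintf("'%s': input contains non-finite values", tau)))
  }
  ok_domain <- switch(tau,
    ln = all(x > 0),
    sqrt = all(x >= 0),
    factorial = all(x >= 0),
    TRUE
  )
  if (!ok_domain) {
    return(cs_rejection("domain", sprintf("'%s' not defined on the observed range", tau)))
  }
  out <- switch(tau,
    identity = x,
    ln = log(x),
    sqrt = sqrt(x),
    exp = exp(x),
    squared = x^2,
    cubed = x^3,
    factorial = exp(lgamma(x + 1)),
    arcsinh = asinh(x)
  )
  if (any(!is.finite(out)) || any(abs(out) > bound)) {
    return(cs_rejection("bound", sprintf("'%s' exceeds the bound c = %g", tau, bound)))
  }
  out
}

cs_rejection <- function(rule, message) {
  structure(list(rule = rule, message = message), class = "cs_rejection")
}

#' Test for a transformation rejection
#' @param x Object to test.
#' @export
is_rejection <- function(x) inherits(x, "cs_rejection")

#' @export
print.cs_rejection <- function(x, ...) {
  cat(sprintf("<rejected transformation> [%s] %s\n", x$rule, x$message))
  invisible(x)
}

#' Build the transformed design for a specification
#'
#' Selects the factors with `alpha = 1`, transforms each per its `tau`, and
#' appends the always-present intercept column. If any selected transformation
#' is rejected the design is flagged infeasible so the search can penalize the
#' specification; nothing is thrown.
#'
#' @param dataset A [count_dataset()].
#' @param spec A [specification()].
#' @param bound Positive bound `c` on transformed values.
#' @return A list of class `cs_design`: `X` (n x (1 + p) model matrix,
#'   intercept first), `feasible`, `rejections` (named list of `cs_rejection`),
#'   `factors` (included factor names in order) and `trans` (their
#'   transformations).
#' @export
build_design <- function(dataset, spec, bound = 1e5) {
  stopifnot(inherits(dataset, "count_dataset"), inherits(spec, "count_spec"))
  missing_k <- setdiff(names(spec$alpha), factor_names(dataset))
  if (length(missing_k)) {
    cs_abort(sprintf("specification references unknown factor(s): %s",
                     paste(missing_k, collapse = ", ")), "countspec_config_error")
  }
  sel <- names(spec$alpha)[spec$alpha == 1L]
  cols <- vector("list", length(sel))
  rejections <- list()
  for (j in seq_along(sel)) {
    k <- sel[j]
    out <- apply_transformation(dataset$factors[[k]], spec$trans[[k]], bound)
    if (is_rejection(out)) {
      rejections[[k]] <- out
      cols[[j]] <- rep(NA_real_, dataset$n)
    } else {
      cols[[j]] <- out
    }
  }
  X <- cbind(`(Intercept)` = rep(1, dataset$n),
             if (length(sel)) do.call(cbind, setNames(cols, sel)))
  structure(
    list(X = X, feasible = length(rejections) == 0L, rejections = rejections,
         factors = sel, trans = unname(spec$trans[sel]), bound = bound),
    class = "cs_design"
  )
}
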