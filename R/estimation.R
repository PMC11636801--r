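#' Estimation options
#'
#' @param max_iter Maximum quasi-Newton iterations (default 500).
#' @param reltol Relative tolerance on the objective (default 1e-6).
#' @param restarts Seeded restarts on optimizer failure.
#' @param seed Seed governing restart jitter (the base fit is deterministic).
#' @param centered Mean-center the positive mixing laws (gamma, Lindley)?
#' @param start Optional warm start: a list with named numeric vectors
#'   `omega` (by factor) and scalar `phi`, e.g. carried over from a previous
#'   fit in a repair chain.
#' @param se Standard-error method: `"hessian"` (central-difference Hessian
#'   of the simulated log-likelihood, the reporting default) or `"opg"`
#'   (outer product of the analytic per-observation scores; much faster and
#'   used for the intermediate fits inside a search).
#' @export
fit_control <- function(max_iter = 500, reltol = 1e-6, restarts = 2,
                        seed = 1, centered = FALSE, start = NULL,
                        se = c("hessian", "opg")) {
  list(max_iter = max_iter, reltol = reltol, restarts = restarts,
       seed = seed, centered = centered, start = start, se = match.arg(se))
}

#' Fit one specification by maximum simulated likelihood
#'
#' Maximizes [simulated_loglik()] with a quasi-Newton (BFGS) search from a
#' deterministic start: the fixed part is initialized at the Poisson
#' fixed-effect solution, random-parameter scales at 0.1 and the dispersion
#' at 0.5 (estimated on the log scale). Standard errors come from the inverse
#' of a central-difference Hessian of the simulated log-likelihood at the
#' optimum, falling back to the outer product of numerically differentiated
#' per-observation gradients (OPG) if the Hessian is not invertible; if both
#' fail, p-values of removable terms are set to 1 so the repair step removes
#' the weakest terms first. Infeasible designs or non-convergent fits return
#' `converged = FALSE` with objective `+Inf`.
#'
#' @param dataset A [count_dataset()].
#' @param spec A [specification()].
#' @param draws Optional [halton_draws()]; built on demand (with `hdraws`
#'   draws and burn-in 100) when the specification has random parameters.
#' @param hdraws Halton draws per observation when `draws` is not supplied.
#' @param bound Bound `c` on transformed values.
#' @param objective Criterion reported as `$objective`: `"BIC"`, `"AIC"` or
#'   `"LL"`.
#' @param control A [fit_control()] list.
#' @return Object of class `count_fit`; see [tidy.count_fit()] and
#'   [glance.count_fit()].
#' @examples
#' d <- count_dataset(data.frame(y = c(1, 2, 3), A = c(0, 0, 0)), "y")
#' f <- fit_spec(d, specification("A"))   # intercept-only Poisson
#' f$coefficients$estimate[1]             # log(2)
#' @export
fit_spec <- function(dataset, spec, draws = NULL, hdraws = 200, bound = 1e5,
                     objective = "BIC", control = fit_control()) {
  spec_n <- spec
  design <- build_design(dataset, spec_n, bound)
  rnd <- names(spec_n$rand)[spec_n$rand == 1L]
  n_r <- length(rnd)
  disp <- has_dispersion(spec_n$model)

  failed <- function(reason) {
    structure(list(spec = spec_n, coefficients = empty_coef_table(),
                   loglik = -Inf, zeta = spec_zeta(spec_n),
                   objective_kind = objective, objective = Inf,
                   converged = FALSE, failure = reason, n = dataset$n,
                   model = spec_n$model, design = design,
                   se_method = "none", iterations = 0L, restarts_used = 0L,
                   hdraws = if (n_r) hdraws else 0L),
              class = "count_fit")
  }
  if (!design$feasible) return(failed("infeasible design"))

  if (n_r > 0 && (is.null(draws) || draws$n_dims < n_r || draws$n_obs != dataset$n)) {
    draws <- halton_draws(dataset$n, hdraws, n_r)
  }
  if (n_r > 0) hdraws <- draws$n_draws

  y <- dataset$response
  X <- design$X
  p <- ncol(X)

  start_b <- tryCatch({
    g <- suppressWarnings(glm.fit(X, y, family = poisson(),
                                  offset = dataset$offset %||% rep(0, dataset$n)))
    co <- g$coefficients
    co[!is.finite(co)] <- 0
    co
  }, error = function(e) c(log(max(mean(y), 0.05)), rep(0, p - 1)))
  om0 <- rep(0.1, n_r)
  phi0 <- 0.5
  if (!is.null(control$start)) {
    ws <- control$start
    if (n_r && !is.null(ws$omega)) {
      hit <- intersect(names(ws$omega), rnd)
      om0[match(hit, rnd)] <- pmax(abs(ws$omega[hit]), 1e-3)
    }
    if (disp && !is.null(ws$phi) && is.finite(ws$phi) && ws$phi > 0) phi0 <- ws$phi
  }
  par0 <- c(start_b, om0, if (disp) log(phi0))
  npar <- length(par0)

  unpack <- function(par) {
    list(b = par[seq_len(p)],
         omega = if (n_r) abs(par[p + seq_len(n_r)]) else numeric(0),
         phi = if (disp) exp(par[npar]) else 0)
  }
  # fast objective + analytic score: precomputes the quantile bases of the
  # linear-in-scale mixing laws once; agrees with simulated_loglik() by
  # construction
  engine <- make_loglik(dataset, design, spec_n, draws, control$centered)
  nll <- function(par) {
    if (any(!is.finite(par)) || (disp && par[npar] > 25)) return(1e10)
    ll <- tryCatch(engine$loglik(unpack(par)), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  gr_nll <- function(par) {
    if (any(!is.finite(par)) || (disp && par[npar] > 25)) return(numeric(npar))
    sc <- tryCatch(engine$score(unpack(par), par[p + seq_len(n_r)]),
                   error = function(e) NULL)
    if (is.null(sc) || !is.finite(sc$ll) || any(!is.finite(sc$gradient))) {
      return(numeric(npar))
    }
    -sc$gradient
  }

  opt <- NULL
  restarts_used <- 0L
  jitter_seeds <- derive_seeds(control$seed, control$restarts + 1L)
  for (attempt in 0:control$restarts) {
    par_try <- par0
    if (attempt > 0) {
      set.seed(jitter_seeds[attempt])
      par_try <- par0 + rnorm(npar, sd = 0.5)
      restarts_used <- attempt
    }
    res <- tryCatch(
      optim(par_try, nll, gr = gr_nll, method = "BFGS",
            control = list(maxit = control$max_iter, reltol = control$reltol)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && res$value < 1e9) { opt <- res; break }
  }
  if (is.null(opt)) return(failed("optimizer did not converge"))

  est <- opt$par
  pars <- unpack(est)
  loglik <- -opt$value
  zeta <- spec_zeta(spec_n)

  # standard errors: central-difference Hessian (reporting default) with the
  # analytic-score OPG as the fast alternative / fallback
  hess_vcov <- function() tryCatch({
    H <- pracma::hessian(nll, est)
    V <- solve(H)
    if (any(!is.finite(diag(V))) || any(diag(V) <= 0)) stop("bad hessian")
    V
  }, error = function(e) NULL)
  opg_vcov <- function() tryCatch({
    G <- engine$score(unpack(est), est[p + seq_len(n_r)])$scores
    V <- solve(crossprod(G))
    if (any(!is.finite(diag(V))) || any(diag(V) <= 0)) stop("bad opg")
    V
  }, error = function(e) NULL)
  se_pref <- control$se %||% "hessian"
  if (se_pref == "hessian") {
    se_method <- "hessian"
    V <- hess_vcov()
    if (is.null(V)) { se_method <- "opg"; V <- opg_vcov() }
  } else {
    se_method <- "opg"
    V <- opg_vcov()
    if (is.null(V)) { se_method <- "hessian"; V <- hess_vcov() }
  }
  if (is.null(V)) se_method <- "none"

  se <- if (!is.null(V)) sqrt(diag(V)) else rep(NA_real_, npar)
  # parameter-space -> reporting scale: |omega| has unit |d|/d|, phi = exp(lphi)
  est_rep <- unname(c(pars$b, pars$omega, if (disp) pars$phi))
  se_rep <- se
  if (disp && !is.null(V)) se_rep[npar] <- pars$phi * se[npar]
  z <- est_rep / se_rep
  pval <- 2 * pnorm(-abs(z))
  if (se_method == "none") {
    pval <- rep(1, npar)  # repair will strip the weakest terms
  }

  coefs <- tibble::tibble(
    term = c("(Intercept)", design$factors,
             if (n_r) paste0(rnd, " (scale)"),
             if (disp) "(Dispersion)"),
    role = c("intercept", rep("coefficient", p - 1L),
             rep("scale", n_r), if (disp) "dispersion"),
    factor = c(NA_character_, design$factors, rnd, if (disp) NA_character_),
    transformation = c(NA_character_, design$trans,
                       unname(spec_n$trans[rnd]), if (disp) NA_character_),
    distribution = c(rep(NA_character_, p), unname(spec_n$dist[rnd]),
                     if (disp) NA_character_),
    estimate = est_rep,
    std.error = se_rep,
    statistic = z,
    p.value = pval
  )

  fit <- structure(
    list(spec = spec_n, coefficients = coefs, loglik = loglik, zeta = zeta,
         objective_kind = objective,
         objective = information_criterion(loglik, zeta, dataset$n, objective),
         bic = information_criterion(loglik, zeta, dataset$n, "BIC"),
         aic = information_criterion(loglik, zeta, dataset$n, "AIC"),
         converged = opt$convergence == 0, failure = NULL, n = dataset$n,
         model = spec_n$model, design = design, se_method = se_method,
         iterations = opt$counts[["function"]], restarts_used = restarts_used,
         hdraws = if (n_r) hdraws else 0L),
    class = "count_fit")
  if (!fit$converged) fit$objective <- Inf
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closure computing the simulated log-likelihood for one design, with the
# per-dimension quantile transforms hoisted out of the optimizer loop.
# normal/uniform/triangular deviates are omega * (precomputed base); gamma and
# Lindley quantiles depend nonlinearly on omega and are evaluated per call.
make_loglik <- function(dataset, design, spec, draws, centered = FALSE) {
  y <- dataset$response
  X <- design$X
  offset <- dataset$offset
  n <- dataset$n
  rnd <- names(spec$rand)[spec$rand == 1L]
  model <- spec$model
  disp <- has_dispersion(model)

  if (!length(rnd)) {
    lgy0 <- lgamma(y + 1)
    mc <- match(model, cs_model_types()) - 1L
    yd0 <- as.numeric(y)
    zero_dev <- matrix(0, n, 1L)
    ll0 <- function(params) {
      eta <- drop(X %*% params$b)
      if (!is.null(offset)) eta <- eta + offset
      sum(count_pmf(y, clamp_rate(exp(eta)), if (disp) params$phi else 0,
                    model, log = TRUE))
    }
    sc0 <- function(params, omega_par) {
      eta0 <- drop(X %*% params$b)
      if (!is.null(offset)) eta0 <- eta0 + offset
      sc <- msl_score_cpp(eta0, zero_dev, yd0,
                          if (disp) params$phi else 0, mc, lgy0, list())
      list(ll = sum(sc$ll),
           gradient = c(drop(crossprod(X, sc$Eg)), if (disp) sum(sc$Ephi)),
           scores = cbind(X * sc$Eg, if (disp) sc$Ephi))
    }
    return(list(loglik = ll0, score = sc0))
  }

  H <- draws$n_draws
  dims <- lapply(seq_along(rnd), function(d) {
    k <- rnd[d]
    u <- as.vector(draws$u[, , d])
    dist <- spec$dist[[k]]
    base <- switch(dist,
      normal = qnorm(u),
      uniform = 2 * u - 1,
      triangular = qtri_sym(u),
      NULL)
    # linear-in-scale laws: deviate = omega * base, with the factor column
    # already folded in; gamma/Lindley quantiles depend nonlinearly on omega
    # and are interpolated through a fixed normal-score grid per call
    zq <- NULL; z_grid <- NULL
    if (is.null(base)) {
      zq <- qnorm(u)
      z_grid <- seq(min(zq), max(zq), length.out = 513L)
    }
    list(k = k, dist = dist, u = u,
         xbase = if (!is.null(base)) X[, k] * matrix(base, n, H),
         zq = zq, z_grid = z_grid, u_grid = if (!is.null(z_grid)) pnorm(z_grid),
         x = X[, k])
  })
  lgy <- lgamma(y + 1)
  model_code <- match(model, cs_model_types()) - 1L
  yd <- as.numeric(y)

  dev_dim <- function(dm, om) {
    # n x H matrix of deviates for one dimension at scale om
    if (!is.null(dm$xbase)) return(om * dm$xbase)  # x folded in
    q_grid <- mixing_deviate(dm$dist, dm$u_grid, om, centered = centered)
    dev <- stats::approx(dm$z_grid, q_grid, xout = dm$zq, rule = 2)$y
    dm$x * matrix(dev, n, H)
  }
  eta_parts <- function(params) {
    eta0 <- drop(X %*% params$b)
    if (!is.null(offset)) eta0 <- eta0 + offset
    devsum <- matrix(0, n, H)
    for (d in seq_along(dims)) {
      devsum <- devsum + dev_dim(dims[[d]], abs(params$omega[d]))
    }
    list(eta0 = eta0, devsum = devsum)
  }

  loglik <- function(params) {
    ep <- eta_parts(params)
    msl_loglik_cpp(ep$eta0, ep$devsum, yd, if (disp) params$phi else 0,
                   model_code, lgy)
  }

  # analytic score: d eta / d omega_d is the precomputed base for the
  # linear-in-scale laws, and a central difference on the deviate matrix for
  # gamma / Lindley; omega enters as |omega|, so the chain rule carries
  # sign(omega_par)
  score <- function(params, omega_par) {
    ep <- eta_parts(params)
    xb <- lapply(seq_along(dims), function(d) {
      dm <- dims[[d]]
      om <- abs(params$omega[d])
      if (!is.null(dm$xbase)) dm$xbase
      else {
        h <- max(om, 0.05) * 1e-3
        (dev_dim(dm, om + h) - dev_dim(dm, max(om - h, 0))) / (h + min(om, h))
      }
    })
    sc <- msl_score_cpp(ep$eta0, ep$devsum, yd,
                        if (disp) params$phi else 0, model_code, lgy, xb)
    grad_b <- drop(crossprod(X, sc$Eg))
    grad_om <- if (length(dims)) {
      colSums(sc$Egz) * ifelse(omega_par == 0, 1, sign(omega_par))
    } else numeric(0)
    grad_phi <- if (disp) sum(sc$Ephi) else numeric(0)
    list(ll = sum(sc$ll), gradient = c(grad_b, grad_om, grad_phi),
         scores = cbind(X * sc$Eg,
                        if (length(dims)) sc$Egz * rep(ifelse(omega_par == 0, 1, sign(omega_par)), each = n),
                        if (disp) sc$Ephi))
  }
  list(loglik = loglik, score = score)
}

empty_coef_table <- function() {
  tibble::tibble(term = character(), role = character(), factor = character(),
                 transformation = character(), distribution = character(),
                 estimate = numeric(), std.error = numeric(),
                 statistic = numeric(), p.value = numeric())
}

per_obs_loglik <- function(dataset, design, spec, params, draws, centered = FALSE) {
  y <- dataset$response
  eta0 <- drop(design$X %*% params$b)
  if (!is.null(dataset$offset)) eta0 <- eta0 + dataset$offset
  rnd <- names(spec$rand)[spec$rand == 1L]
  phi <- if (has_dispersion(spec$model)) params$phi else 0
  if (!length(rnd)) {
    return(count_pmf(y, clamp_rate(exp(eta0)), phi, spec$model, log = TRUE))
  }
  H <- draws$n_draws
  eta <- matrix(eta0, nrow = dataset$n, ncol = H)
  for (d in seq_along(rnd)) {
    k <- rnd[d]
    dev <- matrix(mixing_deviate(spec$dist[[k]], as.vector(draws$u[, , d]),
                                 abs(params$omega[d]), centered = centered),
                  nrow = dataset$n, ncol = H)
    eta <- eta + design$X[, k] * dev
  }
  lp <- matrix(count_pmf(rep(y, H), as.vector(clamp_rate(exp(eta))), phi,
                         spec$model, log = TRUE),
               nrow = dataset$n, ncol = H)
  log_mean_exp_rows(lp)
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("<count_fit> %s, lnL = %.4f, zeta = %d, %s = %.4f%s\n",
              x$model, x$loglik, x$zeta, x$objective_kind, x$objective,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Significance-driven repair of a specification
#'
#' Mimics the ad-hoc pruning an analyst performs after estimation: fit the
#' specification; while any removable estimate has a p-value above
#' `alpha_sig`, drop the single worst offender (largest p-value) and re-fit;
#' stop when all remaining estimates are significant or only the intercept
#' remains. The removal hierarchy honors the constraint that a random
#' parameter requires its fixed effect: an insignificant scale `omega_k`
#' demotes the factor to a fixed effect (`r_k = 0`); an insignificant
#' coefficient `b_k` of a random factor removes the factor entirely. The
#' intercept and the dispersion parameter are never removed. Factors whose
#' inclusion/randomness is forced by the pre-specification of `space` are
#' exempt.
#'
#' @param dataset A [count_dataset()].
#' @param spec The proposal to repair.
#' @param draws Optional [halton_draws()] shared across re-fits.
#' @param alpha_sig Significance level retained terms must meet (default 0.1,
#'   the usual reporting star threshold).
#' @param drop_all Drop every insignificant term per pass instead of the
#'   single worst (faster, but can discard jointly significant terms).
#' @param space Optional [search_space()] whose pre-specification clamps are
#'   honored (forced terms are never dropped).
#' @inheritParams fit_spec
#' @return The final `count_fit`, whose `$spec` is the repaired chromosome.
#' @export
repair_spec <- function(dataset, spec, draws = NULL, alpha_sig = 0.1,
                        drop_all = FALSE, space = NULL, hdraws = 200,
                        bound = 1e5, objective = "BIC",
                        control = fit_control()) {
  if (!is.null(space)) spec <- normalize_spec(spec, space)
  ps <- if (!is.null(space)) space$prespec else prespecification()
  forced_in <- names(ps$include)[ps$include == 1L]
  forced_rand <- names(ps$random)[ps$random == 1L]

  current <- spec
  best_converged <- NULL
  max_pass <- sum(spec$alpha) + sum(spec$rand) + 1L
  fit <- NULL
  ctrl <- control
  for (pass in seq_len(max_pass)) {
    fit <- fit_spec(dataset, current, draws = draws, hdraws = hdraws,
                    bound = bound, objective = objective, control = ctrl)
    if (!fit$converged) {
      if (!is.null(best_converged)) {
        best_converged$repair_failed <- TRUE
        return(best_converged)
      }
      return(fit)
    }
    best_converged <- fit
    cand <- fit$coefficients
    cand <- cand[cand$role %in% c("coefficient", "scale"), , drop = FALSE]
    # analyst-forced terms are not removable
    removable <- cand[!(cand$role == "coefficient" & cand$factor %in% c(forced_in, forced_rand)) &
                      !(cand$role == "scale" & cand$factor %in% forced_rand), , drop = FALSE]
    offenders <- removable[removable$p.value > alpha_sig, , drop = FALSE]
    if (nrow(offenders) == 0L) return(fit)
    if (!drop_all) {
      offenders <- offenders[which.max(offenders$p.value), , drop = FALSE]
    }
    for (i in seq_len(nrow(offenders))) {
      k <- offenders$factor[i]
      if (offenders$role[i] == "scale") {
        current$rand[k] <- 0L
      } else {
        current$alpha[k] <- 0L
        current$rand[k] <- 0L
      }
    }
    current <- if (!is.null(space)) normalize_spec(current, space) else canonicalize_bare(current)
    # warm-start the re-fit at the surviving scales / dispersion
    co <- fit$coefficients
    ctrl$start <- list(
      omega = setNames(co$estimate[co$role == "scale"],
                       co$factor[co$role == "scale"]),
      phi = if (any(co$role == "dispersion")) co$estimate[co$role == "dispersion"])
  }
  fit
}

# canonical form without analyst clamps (used when repair runs outside a space)
canonicalize_bare <- function(spec) {
  spec$alpha[spec$rand == 1L] <- 1L
  spec$dist[spec$rand == 0L] <- cs_distributions()[1]
  spec$trans[spec$alpha == 0L] <- "identity"
  spec
}
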