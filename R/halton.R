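#' Halton low-discrepancy sequence
#'
#' Radical-inverse sequence in a prime base, the quasi-random draws used by
#' the maximum simulated likelihood engine. Entries `burn_in + 1` through
#' `burn_in + n` of the sequence are returned; all values lie strictly in
#' (0, 1) and the output is fully deterministic given `base` and `burn_in`.
#'
#' @param base Prime base.
#' @param n Number of points.
#' @param burn_in Number of initial points to discard (reduces startup
#'   correlation across dimensions).
#' @return Numeric vector of length `n` in (0, 1).
#' @examples
#' halton_sequence(2, 4)   # 0.5 0.25 0.75 0.125
#' @export
halton_sequence <- function(base, n, burn_in = 0) {
  if (length(base) != 1L || base < 2 || !is_prime(base)) {
    cs_abort(sprintf("base must be prime, got %s", base), "countspec_config_error")
  }
  if (n < 1) cs_abort("n must be >= 1", "countspec_config_error")
  idx <- (burn_in + 1):(burn_in + n)
  r <- numeric(n)
  f <- 1
  d <- idx
  while (any(d > 0)) {
    f <- f / base
    r <- r + f * (d %% base)
    d <- d %/% base
  }
  r
}

is_prime <- function(p) {
  p <- as.integer(p)
  if (p < 2L) return(FALSE)
  if (p < 4L) return(TRUE)
  if (p %% 2L == 0L) return(FALSE)
  if (p < 9L) return(TRUE)
  all(p %% seq(3L, floor(sqrt(p)), by = 2L) != 0L)
}

# first n primes, for per-dimension Halton bases
halton_bases <- function(n) {
  ps <- pracma::primes(max(100L, n * 15L))
  ps[seq_len(n)]
}

#' Quasi-random draw set for simulated likelihood
#'
#' One Halton dimension per random parameter, prime bases assigned in order
#' (2, 3, 5, ...), a common burn-in, no scrambling: the draw array is
#' identical across runs and platforms. Each observation receives a
#' consecutive block of `n_draws` points from each dimension's sequence.
#'
#' @param n_obs Number of observations.
#' @param n_draws Halton draws per observation (`Hdraws`, default 200).
#' @param n_dims Number of random-parameter dimensions to prepare.
#' @param burn_in Points discarded from the start of each sequence.
#' @return Object of class `cs_draws`: array `u` of dim
#'   `c(n_obs, n_draws, n_dims)` plus the generation settings.
#' @export
halton_draws <- function(n_obs, n_draws = 200, n_dims = 1, burn_in = 100) {
  stopifnot(n_obs >= 1, n_draws >= 1, n_dims >= 0)
  u <- array(NA_real_, dim = c(n_obs, n_draws, max(n_dims, 1L)))
  if (n_dims > 0) {
    bases <- halton_bases(n_dims)
    for (d in seq_len(n_dims)) {
      s <- halton_sequence(bases[d], n_obs * n_draws, burn_in)
      # observation-major blocks: obs i gets points (i-1)*H + 1 .. i*H
      u[, , d] <- matrix(s, nrow = n_obs, ncol = n_draws, byrow = TRUE)
    }
  }
  structure(list(u = u, n_obs = n_obs, n_draws = n_draws, n_dims = n_dims,
                 bases = if (n_dims > 0) halton_bases(n_dims) else integer(0),
                 burn_in = burn_in),
            class = "cs_draws")
}
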