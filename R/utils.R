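#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`
#' and restores the caller's RNG state afterwards, so library functions
#' never perturb an enclosing simulation stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible vector of sub-seeds from one master seed
#'
#' All repeated or multi-stage computations in the package draw their
#' per-stage seeds through this function, so a single integer seed makes
#' the whole pipeline reproducible while keeping stages independent.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seeds(42, 3)
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed), n >= 0)
  if (n == 0) return(integer(0))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Truncated normal draws via inverse-CDF; deterministic under the current
# RNG stream. Bounds may be infinite.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Shannon entropy (bits) of a nonnegative weight vector; 0 log 0 = 0.
entropy_bits <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
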