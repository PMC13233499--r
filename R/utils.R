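# Internal helpers: seeded evaluation and deterministic child seeds.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state, so seeded package internals do
#' not perturb user-level random streams.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic child seed
#'
#' One master seed per session; children are derived by hashing the master
#' seed with small structural indices (run, trial, repeat ...) through a
#' 32-bit linear congruential step, keeping every derived seed in
#' `[0, 2^31 - 1]`.
#'
#' @param seed master integer seed.
#' @param ... integer indices identifying the child stream.
#' @return integer seed.
#' @keywords internal
#' @noRd
childSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# stopifnot with a friendlier message
.check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
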