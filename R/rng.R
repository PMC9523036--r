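#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `expr`, and restores the caller's
#' `.Random.seed`, so seeded package functions never disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with any number of integer components (sequence
#' index, digit position, phase tag, ...) so that each component of a run
#' gets its own independent, replayable stream.  A single master seed thus
#' fans out to named sub-seeds for frames, masks, weights and orders.
#'
#' @param seed master integer seed.
#' @param ... further integer components.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed) %% m
  for (k in c(...)) {
    h <- (h * 48271 + as.double(k) * 16807 + 12345) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
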