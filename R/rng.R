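# Hierarchical seed derivation. A single base seed spawns named sub-streams
# so that every random component (baseline draw, traits, biases, counts, ...)
# can be regenerated in isolation and so that changing one component's
# distribution never shifts the draws of another.

#' Derive a sub-stream seed from a base seed and a key path
#'
#' Deterministically folds a sequence of tokens (strings or numbers) into a
#' 31-bit integer seed. Used throughout the package to give each random
#' component of a simulation its own reproducible stream.
#'
#' @param seed Integer base seed.
#' @param ... Tokens (character or numeric) identifying the sub-stream, e.g.
#'   `mix_seed(s, "eps", j)` for row `j` of the interaction error matrix.
#' @return An integer in `[0, 2^31)`, suitable for [set.seed()].
#' @export
#' @examples
#' mix_seed(1, "baseline")
#' mix_seed(1, "eps", 3L)
mix_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483629  # largest prime below 2^31
  h <- abs(as.double(seed)) %% m
  for (tok in list(...)) {
    chars <- utf8ToInt(paste(format(tok, digits = 15L), collapse = "|"))
    for (v in chars) h <- (h * 31 + v + 1) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
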