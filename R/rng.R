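# Deterministic seed substreams.  One user-facing seed expands into
# independent per-stage streams so that any stage can be rerun in isolation
# and no stage draws from a global generator.

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' Hashes the base seed together with an arbitrary sequence of labels
#' (stage names, subject indices, states, ...) into a 31-bit integer seed.
#' The hash is a plain polynomial string hash, fully portable across
#' platforms and R versions.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "events", 3) == derive_seed(1, "events", 3)
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  s <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 127 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
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
  force(expr)
}
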