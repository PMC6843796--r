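# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are pure functions of
#' their `seed` argument and never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Documented seed-splitting rule: sub-stream k of a generator seeded with s
# uses the seed (s * 48271 + k) mod (2^31 - 1). Keeps derived seeds in the
# 32-bit integer range and makes each sub-series independently reproducible.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

stop_hazedea <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hazedea_error")))
}
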