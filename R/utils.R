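# Single-seed policy: one run seed deterministically derives the seed of
# every stochastic component, so an end-to-end run is reproducible from a
# single integer.

#' Derive a component seed from a run seed
#'
#' @param seed integer run seed.
#' @param ... component keys (strings and/or integers) identifying the
#'   consumer, e.g. \code{derive_seed(seed, "phantom", subject)}.
#' @return a deterministic integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    v <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
         else as.numeric(k)
    h <- (h * 48271 + v + 1) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
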