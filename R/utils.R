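# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. All stochastic operations in the package funnel through
# this so that a given seed is bit-reproducible.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stage offset, kept inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

stop_ensdm <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ensdm_error")))
}
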