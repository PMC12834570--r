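# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr against the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Derive a child seed from a parent seed and a stage label, keeping the
# result a valid 32-bit integer. Used so one pipeline seed drives every
# stage reproducibly without the stages sharing a stream.
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
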