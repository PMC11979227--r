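# Internal helpers shared across the package.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  force(code)
}

# Derive a child seed from a base seed and a stream index; stays < 2^31.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %%
               2147483629 + 1)
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
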