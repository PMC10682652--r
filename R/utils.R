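# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vp <- function(...) stop(sprintf(...), call. = FALSE)

# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed (kept within 32-bit integer range).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1009 + 97 * k) %% 2147483647
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
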