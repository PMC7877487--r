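# Internal RNG helpers: seed a computation reproducibly without clobbering the
# caller's RNG state, and derive bounded per-stream child seeds from a master.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic child seed in [1, 2^31 - 2]; exact in double arithmetic
# because the intermediate product stays far below 2^53.
derive_seed <- function(master, stream) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(stream) * 7919 + 1
  as.integer(s %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
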