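#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seeds: every stochastic stage (simulation of block i,
# bootstrap, ...) derives its own seed from one top-level seed so stages are
# independently reproducible. Kept inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  ((as.double(seed) %% 2147483647) * 48271 + as.double(stream)) %% 2147483629 + 1
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
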