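# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL runs `code` on the current stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  code
}

# Deterministic substream seed derived from a master seed.  Subject i's
# substream does not depend on how many other subjects exist, so per-subject
# data are invariant to cohort size.  Kept strictly inside 32-bit range.
sub_seed <- function(master, i, stream = 0L) {
  m <- 2147483647
  x <- (as.numeric(master) %% m) * 48271 + as.numeric(i) * 7919 +
    as.numeric(stream) * 104729
  as.integer(x %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}
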