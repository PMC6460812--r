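# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulators never perturb the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# log(sum(exp(x))) without overflow/underflow; x may contain -Inf.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
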