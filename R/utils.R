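# Internal helpers shared across modules.

# Set the RNG locally for a call when `seed` is given, restoring the caller's
# stream on exit. Keeps every stochastic entry point reproducible from one
# integer without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Deterministic child seeds derived from one parent seed; keeps sub-generators
# independent while reproducible. Values stay below 2^31.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

# Population standard deviation (divide by N, not N-1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Circular difference of two phases on a cycle of length `period`, in [0, period/2].
circ_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Circular midpoint of two phases, returned on [0, period).
circ_midpoint <- function(a, b, period = 24) {
  w <- 2 * pi / period
  (Arg(exp(1i * w * a) + exp(1i * w * b)) / w) %% period
}

`%||%` <- function(a, b) if (is.null(a)) b else a
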