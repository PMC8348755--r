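# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers never observe a side effect.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic stream seed from a base seed and a few small indices.
# Kept below 2^31 - 1 so it is always a valid set.seed() argument; the
# multipliers are coprime so distinct (subject, record, state) tuples get
# distinct streams for any base seed of practical size.
mix_seed <- function(seed, ...) {
  idx <- c(...)
  v <- (as.numeric(seed) %% 2147483647) * 69069
  mult <- c(1234567, 7654321, 2718281, 3141593, 1618033)
  for (i in seq_along(idx)) {
    v <- v + as.numeric(idx[i]) * mult[((i - 1L) %% length(mult)) + 1L]
  }
  as.integer(v %% 2147483646) + 1L
}

# Stop with a classed condition so tests can assert on error types.
stop_seiznet <- function(msg, class) {
  stop(structure(
    class = c(class, "seiznet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
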