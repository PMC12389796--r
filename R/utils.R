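`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed derived from a parent seed and integer tags,
# kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 1000003 + (as.numeric(t) %% 2147483647)) %% 2147483629
  as.integer(h)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
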