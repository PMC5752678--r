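# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible substream seed from a base seed and a counter,
# kept within the 32-bit integer range.
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 1009 + counter * 9973) %% 2147483647)
}

geomean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)
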