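# internal helpers shared across modules

# divisor converting natural-log entropies to the requested base
.logdiv <- function(log_base) {
  if (identical(log_base, "e")) return(1)
  if (identical(log_base, "2")) return(log(2))
  if (is.numeric(log_base) && length(log_base) == 1L && log_base > 0 &&
      log_base != 1) {
    return(log(log_base))
  }
  stop("log_base must be 2 or \"e\" (or a positive numeric base != 1)")
}

# Matlab-style rounding: halves go away from zero, not to even
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# x * log(x) with the 0 * log(0) = 0 convention, vectorized
.xlogx <- function(x) {
  y <- numeric(length(x))
  pos <- x > 0
  y[pos] <- x[pos] * log(x[pos])
  y
}

.check_scalar_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha)) {
    stop("alpha must be a single finite number")
  }
  if (alpha < 0) stop("alpha must be non-negative")
  invisible(alpha)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.is_count_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(is.finite(x)) && all(x >= 0) &&
    all(abs(x - round(x)) < 1e-8)
}
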