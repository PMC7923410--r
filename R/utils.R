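# Internal helpers shared across modules.

# Population (divisor N) variance / SD: the convention of the printed
# time-domain formulas. `sample = TRUE` switches to divisor N-1.
pop_var <- function(x, sample = FALSE) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values for a variance", call. = FALSE)
  v <- sum((x - mean(x))^2)
  v / (if (sample) n - 1L else n)
}

pop_sd <- function(x, sample = FALSE) sqrt(pop_var(x, sample = sample))

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Cumulative trapezoidal integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

# Evaluate an expression with a temporary RNG state seeded at `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a character representation; used to stamp pipeline outputs
# with the exact configuration they were produced under.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime in 16-bit halves (doubles stay exact)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_validation <- function(...) stop(sprintf(...), call. = FALSE)
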