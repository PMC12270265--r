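# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Deterministic sub-seed below 2^31 derived from a master seed and an index,
# so per-group RNG streams are independent of group processing order.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m)
  h <- (s * 48271 + as.double(index) * 1000003 + 12345) %% m
  as.integer(h) + 1L
}

# Largest-remainder apportionment of n items to the given fractions: the
# returned integer counts sum to n exactly and each is within 1 of frac*n.
round_counts <- function(fracs, n) {
  stopifnot(all(fracs >= 0), n >= 0)
  target <- fracs * n
  base <- floor(target)
  short <- as.integer(round(n - sum(base)))
  if (short > 0) {
    rem <- target - base
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

stop_input <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("grsim_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
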