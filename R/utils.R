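# Internal helpers: deterministic seed substreams and small validators.

# Lehmer-style integer mixing; keeps every derived seed in [1, 2^31 - 2] so
# it is always a valid argument to set.seed() on 32-bit integers.
.mix_seed <- function(seed, ...) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (v in c(...)) {
    s <- (s * 48271 + abs(as.numeric(v)) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# Run `expr` under a local RNG stream: the caller's .Random.seed is restored
# on exit so seeded package functions do not perturb user-level randomness.
.with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must lie in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

.assert_count <- function(x, name, lower = 1L) {
  .assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be an integer, got %s", name, x), call. = FALSE)
  }
  invisible(as.integer(x))
}
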