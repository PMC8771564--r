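# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate expr with a temporary RNG state seeded by `seed`; NULL = use the
# current stream. The caller's .Random.seed is restored afterwards.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Centered rolling extremum with truncated windows at the trace edges.
rollExtreme <- function(x, w, fun) {
  n <- length(x)
  h <- w %/% 2L
  vapply(seq_len(n), function(i) fun(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

# Cubic smoothstep on [0, 1].
smoothstep <- function(u) {
  u <- clamp(u, 0, 1)
  u * u * (3 - 2 * u)
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
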