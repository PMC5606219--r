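# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Comparison operator lookup used by the filter algebra ({<, <=, ==, >=, >}).
op_fun <- function(op) {
  ops <- list("<" = `<`, "<=" = `<=`, "=" = `==`, "==" = `==`,
              ">=" = `>=`, ">" = `>`)
  f <- ops[[op]]
  if (is.null(f)) stop("unknown comparison operator: ", op, call. = FALSE)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-open interval overlap test, vectorized.
olap <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single number", call. = FALSE)
}
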