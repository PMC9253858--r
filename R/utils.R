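# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All exported stochastic operations route
# through this so a single integer seed fully determines their output without
# clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

# Deterministic stage seed derived from a global seed and a stage name, so
# pipeline stages are independently re-runnable yet reproducible. Plain
# polynomial string hash folded into [0, 2^31 - 1].
derive_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_equal_lower) x >= lower else x > lower) &&
    (if (allow_equal_upper) x <= upper else x < upper)
  if (!ok) stopf("'%s' must be a finite number in %s%s, %s%s (got %s)",
                 name, if (allow_equal_lower) "[" else "(", lower, upper,
                 if (allow_equal_upper) "]" else ")",
                 paste(format(x), collapse = ","))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numeric formatting that survives a CSV round trip exactly.
format_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- ""
  out[!is.na(x)] <- sprintf("%.17g", x[!is.na(x)])
  out
}
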