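# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.  All simulator entry points route randomness through
# this so identical (config, seed) pairs give bit-identical output.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != as.integer(x))
    stop_input(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop_input(sprintf("'%s' must be a single number", name))
  if (if (strict) x <= min else x < min)
    stop_input(sprintf("'%s' must be %s %g", name,
                       if (strict) "greater than" else "at least", min))
  as.numeric(x)
}
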