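# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "pgsperm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

validation_error <- function(fmt, ...) {
  stopf(fmt, ..., class = "pgsperm_validation_error")
}

parse_error <- function(fmt, ...) {
  stopf(fmt, ..., class = "pgsperm_parse_error")
}

assert_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    validation_error("'%s' must be > 0", name)
  invisible(x)
}

# set the RNG deterministically for a generator call without clobbering the
# caller's stream when no seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_number(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
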