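# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# shared input checks -------------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  x
}

check_count <- function(x, field, min = 0L) {
  check_scalar_number(x, field)
  if (x < min || x != round(x))
    stop_field(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field) {
  check_scalar_number(x, field)
  if (x < 0 || x > 1) stop_field(field, "must lie in [0, 1]")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
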