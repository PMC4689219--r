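`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state; restores (or removes) .Random.seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# One user-facing seed deterministically spawns independent child seeds,
# so pipeline stages are individually reproducible.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    stop(sprintf("'%s' must be a numeric value of length %d", name, len),
         call. = FALSE)
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper))
    stop(sprintf("'%s' out of range: must be in %s%g, %g]",
                 name, if (strict_lower) "(" else "[", lower, upper),
         call. = FALSE)
  x
}

check_flag_class <- function(x, what) {
  if (!inherits(x, what))
    stop(sprintf("expected a '%s' object, got '%s'", what, class(x)[1L]),
         call. = FALSE)
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
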