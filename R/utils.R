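#' @keywords internal
"_PACKAGE"

# internal assertion helpers ------------------------------------------------

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (x < min || x > max)
    .stopf("'%s' must be in [%s, %s]", name, format(min), format(max))
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  .check_scalar_number(x, name, min = min)
  if (x != round(x)) .stopf("'%s' must be an integer", name)
  invisible(as.integer(x))
}

# seeded evaluation that never leaks into the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# spread one base seed into per-stage seeds, all < 2^31
.fan_seed <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
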