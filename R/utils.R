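# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
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
  force(code)
}

# Printed tables round half-up, not banker's rounding.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

# dims is always c(width, height) in the user API; rasters are H x W matrices.
check_dims <- function(dims) {
  if (!is.numeric(dims) || length(dims) != 2L || any(dims < 1) ||
      any(dims != floor(dims)))
    stop_f("raster dims must be two positive integers c(width, height)")
  as.integer(dims)
}
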