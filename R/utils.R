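#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG seed, restoring the caller's RNG state.
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
    set.seed(seed)
  }
  force(code)
}

# x %||% y
`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# pixel (x, y) pairs -> unique integer keys within a field of width w
pixel_key <- function(px, w) px[, 1L] + px[, 2L] * w

# inclusive interval intersection test for two (onset, peak) pairs
intervals_intersect <- function(a0, a1, b0, b1) a0 <= b1 & b0 <= a1
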