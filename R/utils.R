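#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; abundance percentages in reports
#' are conventionally rounded half-up (0.125 -> 0.13 at 2 dp), so results
#' match the usual presentation of relative-abundance tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.125, 98.865), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
# Generators must be pure functions of their config, including the seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "mycomix_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(code)
}

stop_invalid <- function(msg) abort(msg, class = "mycomix_invalid_input")
stop_config <- function(msg) abort(msg, class = "mycomix_config_error")
stop_missing_reference <- function(msg) abort(msg, class = "mycomix_missing_reference")
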