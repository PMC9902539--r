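## shared input checks and small helpers

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and > 0.", name), class = "lamellar_domain_error")
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and >= 0.", name), class = "lamellar_domain_error")
  }
  invisible(x)
}

deg2rad <- function(deg) deg * pi / 180

## round-half-even at `digits` (base round() already implements IEC 60559
## banker's rounding for .5 ties)
round_half_even <- function(x, digits = 0) round(x, digits)

#' Run an expression with a private, seeded RNG state
#'
#' All stochastic operations in the package route their draws through this
#' helper so that a given seed always reproduces the same output without
#' disturbing the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "lamellar_domain_error")
  }
  withr::with_seed(as.integer(seed), code)
}
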