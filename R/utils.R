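#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a whole number: 62.5 rounds to 63,
#' 37.5 to 38. Used for reporting suppression percentages, where banker's
#' rounding (the [round()] default) would round 62.5 down to 62.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @return Numeric vector of whole numbers.
#' @export
#' @examples
#' round_half_up(c(62.5, 37.5, 12.49))
round_half_up <- function(x) {
  floor(x + 0.5)
}

# argmax with deterministic lowest-index tie-break
which_max_first <- function(x) {
  which.max(x) # which.max already returns the first maximum
}

# derive a child RNG seed from a parent seed and integer tags, staying
# inside the 32-bit signed range set.seed() accepts
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) {
    s <- (s * 69069 + as.double(t) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "panhar_bad_argument")
  }
  invisible(x)
}
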