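#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats runif
NULL

# Half-up rounding (R's round() is round-half-even); 8-bit display convention.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# All randomness in the package flows through the caller's RNG state; helpers
# that take a `seed` argument set it once via set.seed().
check_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
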