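# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves moving away from zero,
#' the convention used in clinical tables (in contrast to base R's
#' round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, -0.05), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic derived seed for hierarchical random-stream splitting.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483629)
  as.integer((s * 48271 + as.numeric(offset)) %% 2147483647)
}

# Percentage of a count over a denominator, NA when denominator is zero.
pct_of <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

stop_input <- function(msg, ...) abort(msg, class = "cadmrmc_input_error", ...)
stop_schema <- function(msg, ...) abort(msg, class = "cadmrmc_schema_error", ...)

# is x a single finite number
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
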