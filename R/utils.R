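## Small internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic half-up rounding used for reported ratios, avoiding the
#' round-half-to-even behaviour of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.0765, 3)
#' @export
round_half_up <- function(x, digits = 3) {
  stopifnot(is.numeric(x), is.numeric(digits), digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a class so callers/tests can distinguish error families
ih_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "islehaps_error")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x)
}

# Normalize island/population labels: trim whitespace, NFC unicode form.
normalize_label <- function(x) {
  x <- trimws(as.character(x))
  enc2utf8(x)
}
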