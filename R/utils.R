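#' Round half away from zero
#'
#' Decimal rounding with halves moved away from zero (2.675 -> 2.68,
#' -2.675 -> -2.68), the convention used when comparing computed scale
#' values with their printed 2-decimal representations. Base `round()`
#' rounds halves to even, which disagrees on exact midpoints such as
#' 38.125.
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 2.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_up(38.125)  # 38.13
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
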