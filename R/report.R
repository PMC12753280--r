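#' Rounding and percentage reporting rules
#'
#' Endpoints are reported as percentages with mixed precision: values of at
#' least 10% to the nearest integer, values below 10% to one decimal place.
#' Rounding is half-away-from-zero (so 63.5 reports as 64), unlike base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `round_half_away()`: `x` rounded half-away-from-zero.
#'   `percent_points()`: the belief as a number of percentage points under
#'   the mixed-precision rule. `percent_label()`: the same with a `%` suffix.
#' @export
#' @examples
#' round_half_away(63.5)  # 64
#' percent_points(0.6352) # 64
#' percent_points(0.0201) # 2.0
#' percent_label(0.0118)  # "1.2%"
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @rdname round_half_away
#' @param p Probability vector in `[0, 1]`.
#' @export
percent_points <- function(p) {
  check_probability(p, "p")
  pct <- 100 * p
  ifelse(pct >= 10, round_half_away(pct, 0), round_half_away(pct, 1))
}

#' @rdname round_half_away
#' @export
percent_label <- function(p) {
  pct <- percent_points(p)
  ifelse(100 * p >= 10, sprintf("%d%%", as.integer(pct)), sprintf("%.1f%%", pct))
}
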