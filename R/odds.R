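#' Clamp probabilities away from 0 and 1
#'
#' Beliefs are stored as probabilities but updated in odds / log-odds form,
#' which is undefined at exactly 0 or 1. All user-supplied and computed
#' beliefs are therefore clamped to `[1e-12, 1 - 1e-12]`. Values outside
#' `[0, 1]` are not probabilities and raise an error.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param what Name used in error messages.
#' @return `p` clamped to the open unit interval.
#' @export
#' @examples
#' clamp_probability(c(0, 0.5, 1))
clamp_probability <- function(p, what = "p") {
  check_probability(p, what)
  pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)
}

check_probability <- function(p, what = "p", open = FALSE) {
  if (!is.numeric(p) || length(p) == 0 || anyNA(p) || any(!is.finite(p))) {
    abort(sprintf("`%s` must be a finite numeric probability.", what))
  }
  bad <- if (open) p <= 0 | p >= 1 else p < 0 | p > 1
  if (any(bad)) {
    abort(sprintf(
      "`%s` must lie in %s; got %s.",
      what, if (open) "(0, 1)" else "[0, 1]",
      paste(format(p[bad]), collapse = ", ")
    ))
  }
  invisible(p)
}

#' Convert between probability and odds
#'
#' `probability_to_odds()` maps a belief p to odds p / (1 - p);
#' `odds_to_probability()` is its inverse, o / (1 + o). These are the two
#' halves of the odds-form Bayes rule: posterior odds = prior odds x
#' likelihood ratio.
#'
#' @param p Probability vector; clamped to the open unit interval first.
#' @param o Nonnegative, finite odds vector.
#' @return Numeric vector of odds (resp. probabilities).
#' @export
#' @examples
#' probability_to_odds(0.9) # 9: an aTSA Loyalist's 90% prior as odds
#' odds_to_probability(9)
probability_to_odds <- function(p) {
  p <- clamp_probability(p, "p")
  p / (1 - p)
}

#' @rdname probability_to_odds
#' @export
odds_to_probability <- function(o) {
  if (!is.numeric(o) || length(o) == 0 || anyNA(o) || any(!is.finite(o)) || any(o < 0)) {
    abort(sprintf(
      "`o` must be finite nonnegative odds; got %s.",
      paste(format(o[!is.finite(o) | is.na(o) | o < 0]), collapse = ", ")
    ))
  }
  clamp_probability(o / (1 + o), "o/(1+o)")
}
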