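#' Define a bias policy
#'
#' A bias policy controls how each trial's likelihood ratio is weighted
#' before updating. Evidence is first classified as confirming, disconfirming
#' or neutral relative to the decision-maker's current belief and the
#' `threshold` (see [classify_evidence()]); the matching exponent weight is
#' then applied to the likelihood ratio. `w_confirming = w_disconfirming = 1`
#' is unbiased Bayesian updating; `w_disconfirming < 1` is confirmation bias
#' (disconfirming evidence discounted); `w_disconfirming = 0` ignores
#' disconfirming evidence entirely.
#'
#' @param w_confirming Exponent weight in `[0, 1]` for confirming evidence.
#' @param w_disconfirming Exponent weight in `[0, 1]` for disconfirming
#'   evidence. The canonical moderate-bias value is 0.5.
#' @param threshold Belief threshold in `(0, 1)` separating the two favored
#'   treatments; default 0.5 (equipoise).
#' @return An object of class `bias_policy`.
#' @export
#' @examples
#' bias_policy()                        # unbiased
#' bias_policy(w_disconfirming = 0.5)   # moderate confirmation bias
bias_policy <- function(w_confirming = 1, w_disconfirming = 1, threshold = 0.5) {
  check_weight(w_confirming, "w_confirming")
  check_weight(w_disconfirming, "w_disconfirming")
  check_probability(threshold, "threshold", open = TRUE)
  structure(
    list(
      w_confirming = as.numeric(w_confirming),
      w_disconfirming = as.numeric(w_disconfirming),
      threshold = as.numeric(threshold)
    ),
    class = "bias_policy"
  )
}

#' @rdname bias_policy
#' @export
unbiased_policy <- function(threshold = 0.5) {
  bias_policy(1, 1, threshold)
}

check_weight <- function(w, what) {
  if (!is.numeric(w) || length(w) != 1 || is.na(w) || !is.finite(w) ||
      w < 0 || w > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]; got %s.",
                  what, paste(format(w), collapse = ", ")))
  }
  invisible(w)
}

#' @export
print.bias_policy <- function(x, ...) {
  kind <- if (x$w_confirming == 1 && x$w_disconfirming == 1) {
    "unbiased"
  } else {
    "confirmation-biased"
  }
  cat(sprintf(
    "<bias_policy: %s>\n  w_confirming    = %g\n  w_disconfirming = %g\n  threshold       = %g\n",
    kind, x$w_confirming, x$w_disconfirming, x$threshold
  ))
  invisible(x)
}

#' @export
format.bias_policy <- function(x, ...) {
  sprintf("w_conf=%g, w_disc=%g, thr=%g",
          x$w_confirming, x$w_disconfirming, x$threshold)
}
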