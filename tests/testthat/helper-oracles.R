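# Independent closed-form oracle: belief after each trial is the logistic of
# the cumulative sum of weighted log likelihood ratios. Used to cross-check
# the sequential implementation without going through run_sequence().
closed_form_beliefs <- function(prior, lrs, weights = rep(1, length(lrs))) {
  # Reduce, not cumsum: cumsum accumulates in long double, which is not the
  # plain double-precision sequential sum the property asserts
  plogis(Reduce(`+`, weights * log(lrs), init = qlogis(prior), accumulate = TRUE)[-1])
}

# Odds-product oracle for the unbiased rule: posterior odds are prior odds
# times the product of likelihood ratios.
odds_product_final <- function(prior, lrs) {
  o <- (prior / (1 - prior)) * prod(lrs)
  o / (1 + o)
}

# All permutations of a small vector (recursive; fine for length <= 5).
combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}
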