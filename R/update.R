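#' Classify evidence relative to the current belief
#'
#' A trial's likelihood ratio is the probability of its result if treatment A
#' is superior divided by the probability if treatment B is superior, so
#' values above 1 favor A and values below 1 favor B. Evidence is
#' *disconfirming* when it favors the treatment the decision-maker currently
#' believes inferior, *confirming* when it favors the currently favored
#' treatment, and *neutral* when the likelihood ratio is exactly 1.
#'
#' The favored treatment is A when `belief >= threshold` and B otherwise:
#' a belief sitting exactly at the threshold counts as favoring A, so
#' B-favoring evidence at equipoise is disconfirming. Classification always
#' uses the belief *before* the trial's update, so the label of later trials
#' depends on the path the belief has taken (in particular, a single
#' B-favoring trial can push a neutral believer below threshold, after which
#' further B-favoring evidence is confirming).
#'
#' @param belief Current probability that treatment A is superior.
#' @param likelihood_ratio Positive finite likelihood ratio(s), A over B.
#' @param threshold Belief threshold in `(0, 1)`; default 0.5.
#' @return Character vector in `c("confirming", "disconfirming", "neutral")`.
#' @export
#' @examples
#' classify_evidence(0.90, 0.72) # B-favoring trial vs. an A believer
#' classify_evidence(0.10, 0.72) # same trial confirms a B believer
#' classify_evidence(0.50, 0.72) # tie counts as favoring A: disconfirming
classify_evidence <- function(belief, likelihood_ratio, threshold = 0.5) {
  check_probability(belief, "belief", open = TRUE)
  check_probability(threshold, "threshold", open = TRUE)
  check_lr(likelihood_ratio)
  favored_a <- belief >= threshold
  dplyr::case_when(
    likelihood_ratio == 1 ~ "neutral",
    favored_a & likelihood_ratio < 1 ~ "disconfirming",
    !favored_a & likelihood_ratio > 1 ~ "disconfirming",
    TRUE ~ "confirming"
  )
}

check_lr <- function(lr, what = "likelihood_ratio") {
  if (!is.numeric(lr) || length(lr) == 0 || anyNA(lr) ||
      any(!is.finite(lr)) || any(lr <= 0)) {
    abort(sprintf("`%s` must be positive and finite.", what))
  }
  invisible(lr)
}

#' Apply one bias-weighted Bayesian update
#'
#' Performs a single odds-form update: posterior odds equal prior odds times
#' the likelihood ratio raised to the exponent `weight`. `weight = 1` is the
#' plain Bayes rule; `weight < 1` discounts the evidence; `weight = 0`
#' ignores it. The computation runs in log-odds space
#' (`log posterior odds = log prior odds + weight * log LR`) for numerical
#' stability, and the result is clamped away from 0 and 1.
#'
#' @param belief Prior probability that treatment A is superior.
#' @param likelihood_ratio Positive finite likelihood ratio, A over B.
#' @param weight Exponent in `[0, 1]` applied to the likelihood ratio.
#' @return Posterior probability that treatment A is superior.
#' @export
#' @examples
#' apply_update(0.9, 0.72, weight = 1)   # full-strength update
#' apply_update(0.9, 0.72, weight = 0.5) # discounted update
apply_update <- function(belief, likelihood_ratio, weight = 1) {
  belief <- clamp_probability(belief, "belief")
  check_lr(likelihood_ratio)
  check_weight(weight, "weight")
  clamp_probability(plogis(qlogis(belief) + weight * log(likelihood_ratio)))
}

#' Run a sequence of belief updates over an evidence stream
#'
#' Iterates [classify_evidence()] and the bias-weighted odds-form update over
#' an ordered evidence stream: each trial is classified against the belief it
#' meets, the policy's weight for that class is applied, and the posterior
#' becomes the next trial's prior. The running state is kept in log-odds
#' between trials so that repeated updating is exactly a cumulative sum of
#' weighted log likelihood ratios.
#'
#' @param initial Initial probability that treatment A is superior.
#' @param evidence Evidence stream: either a positive numeric vector of
#'   likelihood ratios or a data frame with a `likelihood_ratio` column (and
#'   optionally `trial_id`), as produced by [fixed_stream()],
#'   [mixed_stream()] or [binomial_stream()].
#' @param policy A [bias_policy()]; default unbiased.
#' @return A `belief_trajectory` object: the initial belief, the policy, and
#'   one record per trial (`trial_index`, `trial_id`, `likelihood_ratio`,
#'   `pre_belief`, `classification`, `weight_applied`, `post_belief`).
#'   Access the records with [tidy()], the endpoint summary with [glance()],
#'   or plot with [autoplot()].
#' @export
#' @examples
#' traj <- run_sequence(0.9, fixed_stream(10, 0.72))
#' glance(traj)
#' run_sequence(0.9, fixed_stream(10, 0.72),
#'              bias_policy(w_disconfirming = 0.5))
run_sequence <- function(initial, evidence, policy = unbiased_policy()) {
  stopifnot(inherits(policy, "bias_policy"))
  evidence <- as_evidence(evidence)
  if (nrow(evidence) == 0) {
    abort("`evidence` must contain at least one trial.")
  }
  initial <- clamp_probability(initial, "initial")

  n <- nrow(evidence)
  lr <- evidence$likelihood_ratio
  pre <- post <- weight <- numeric(n)
  classification <- character(n)

  eps_logit <- qlogis(.PROB_EPS)
  state <- qlogis(initial) # log-odds carried across trials
  prev <- initial
  for (k in seq_len(n)) {
    pre[k] <- prev
    classification[k] <- classify_evidence(pre[k], lr[k], policy$threshold)
    weight[k] <- switch(classification[k],
      confirming = policy$w_confirming,
      disconfirming = policy$w_disconfirming,
      neutral = 1
    )
    state <- state + weight[k] * log(lr[k])
    state <- min(max(state, eps_logit), -eps_logit)
    post[k] <- plogis(state)
    prev <- post[k]
  }

  records <- tibble::tibble(
    trial_index = seq_len(n),
    trial_id = evidence$trial_id,
    likelihood_ratio = lr,
    pre_belief = pre,
    classification = classification,
    weight_applied = weight,
    post_belief = post
  )
  structure(
    list(initial_belief = initial, policy = policy, records = records),
    class = "belief_trajectory"
  )
}

as_evidence <- function(evidence) {
  if (is.data.frame(evidence)) {
    if (!"likelihood_ratio" %in% names(evidence)) {
      abort("evidence data frame must have a `likelihood_ratio` column.")
    }
    if (nrow(evidence) > 0) check_lr(evidence$likelihood_ratio)
    tibble::tibble(
      trial_id = evidence$trial_id %||% seq_len(nrow(evidence)),
      likelihood_ratio = as.numeric(evidence$likelihood_ratio)
    )
  } else {
    if (length(evidence) > 0) check_lr(evidence, "evidence")
    tibble::tibble(
      trial_id = seq_along(evidence),
      likelihood_ratio = as.numeric(evidence)
    )
  }
}

#' Final belief of a trajectory
#'
#' @param trajectory A `belief_trajectory`.
#' @return The posterior probability after the last trial.
#' @export
final_belief <- function(trajectory) {
  stopifnot(inherits(trajectory, "belief_trajectory"))
  n <- nrow(trajectory$records)
  if (n == 0) trajectory$initial_belief else trajectory$records$post_belief[n]
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat(sprintf(
    "<belief_trajectory: %d trials, %s>\n  initial belief %.4f -> final belief %.4f\n",
    nrow(x$records), format(x$policy), x$initial_belief, final_belief(x)
  ))
  print(x$records, n = 5)
  invisible(x)
}

#' Tidy a belief trajectory into per-trial records
#'
#' @param x A `belief_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per trial.
#' @export
tidy.belief_trajectory <- function(x, ...) {
  x$records
}

#' One-row summary of a belief trajectory
#'
#' @param x A `belief_trajectory`.
#' @param ... Unused.
#' @return A tibble with the initial and final beliefs, the number of trials,
#'   classification counts, and the final belief as a reported percentage
#'   (see [percent_points()]).
#' @export
glance.belief_trajectory <- function(x, ...) {
  cls <- x$records$classification
  tibble::tibble(
    initial_belief = x$initial_belief,
    final_belief = final_belief(x),
    n_trials = nrow(x$records),
    n_confirming = sum(cls == "confirming"),
    n_disconfirming = sum(cls == "disconfirming"),
    n_neutral = sum(cls == "neutral"),
    final_percent = percent_points(final_belief(x))
  )
}

#' Plot a belief trajectory
#'
#' @param object A `belief_trajectory`.
#' @param ... Unused.
#' @return A ggplot showing belief (0-1) against trial index, starting at
#'   trial 0 (the prior).
#' @export
autoplot.belief_trajectory <- function(object, ...) {
  df <- tibble::tibble(
    trial = c(0, object$records$trial_index),
    belief = c(object$initial_belief, object$records$post_belief)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$belief)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Trial", y = "P(treatment A superior)",
      title = "Belief trajectory",
      subtitle = format(object$policy)
    ) +
    ggplot2::theme_minimal()
}
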