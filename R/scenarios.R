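#' Canonical surgeon archetypes
#'
#' The three canonical decision-maker archetypes for the aTSA-vs-rTSA
#' comparison, defined by their prior probability that anatomic total
#' shoulder arthroplasty (treatment A) is superior: a Loyalist strongly
#' committed to aTSA (0.90), a Neutral Thinker at equipoise (0.50), and an
#' rTSA Advocate (0.10).
#'
#' @return A tibble with columns `name` and `prior`, in Loyalist, Neutral,
#'   Advocate order.
#' @export
#' @examples
#' archetypes()
archetypes <- function() {
  tibble::tibble(
    name = c("aTSA Loyalist", "Neutral Thinker", "rTSA Advocate"),
    prior = c(0.90, 0.50, 0.10)
  )
}

#' Default per-archetype likelihood ratios
#'
#' Constant per-trial likelihood ratios calibrated (to three significant
#' figures or fewer) from each archetype's published unbiased endpoint over
#' ten trials: 0.90 to 25%, 0.50 to 2.0%, 0.10 to 1.2%. The three endpoints
#' are not mutually consistent under any single constant LR (see
#' [implied_lr_report()]), so each archetype carries its own constant.
#'
#' @return A named numeric vector of likelihood ratios.
#' @export
default_archetype_lr <- function() {
  c("aTSA Loyalist" = 0.72, "Neutral Thinker" = 0.678, "rTSA Advocate" = 0.80)
}

#' Compare biased and unbiased belief updating across archetypes
#'
#' Runs the canonical experiment: each archetype reviews the same sequence of
#' B-favoring (rTSA-favoring) trials twice — once updating without bias and
#' once under a confirmation-bias policy that down-weights disconfirming
#' evidence with exponent `w_disconfirming`. Both conditions for a given
#' archetype share the identical evidence stream, so any endpoint difference
#' is attributable to the bias alone.
#'
#' @param lr Named vector mapping each archetype name to its constant
#'   per-trial likelihood ratio; default [default_archetype_lr()].
#' @param n_trials Number of trials; default 10.
#' @param w_disconfirming Bias exponent for disconfirming evidence in the
#'   biased condition; default 0.5.
#' @param threshold Classification threshold; default 0.5.
#' @return A tibble with 2 rows per archetype (`condition` is `"unbiased"`
#'   or `"biased"`): `archetype`, `prior`, `likelihood_ratio`, `condition`,
#'   `final_belief`, `final_percent` (mixed-precision reporting, see
#'   [percent_points()]), and a `trajectory` list column of
#'   `belief_trajectory` objects. The result carries class
#'   `archetype_comparison` and can be plotted with [autoplot()].
#' @export
#' @examples
#' cmp <- archetype_comparison()
#' cmp[, c("archetype", "condition", "final_percent")]
archetype_comparison <- function(lr = default_archetype_lr(), n_trials = 10,
                                 w_disconfirming = 0.5, threshold = 0.5) {
  arch <- archetypes()
  missing <- setdiff(arch$name, names(lr))
  if (length(missing) > 0) {
    abort(sprintf("no likelihood ratio supplied for archetype(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  check_count(n_trials, "n_trials")
  check_weight(w_disconfirming, "w_disconfirming")

  policies <- list(
    unbiased = unbiased_policy(threshold),
    biased = bias_policy(1, w_disconfirming, threshold)
  )
  grid <- tidyr::expand_grid(arch, condition = names(policies))
  trajectories <- purrr::pmap(
    list(grid$prior, grid$name, grid$condition),
    function(p, nm, cond) {
      run_sequence(p, fixed_stream(n_trials, lr[[nm]]), policies[[cond]])
    }
  )
  out <- grid |>
    dplyr::mutate(
      likelihood_ratio = unname(lr[.data$name]),
      trajectory = trajectories,
      final_belief = purrr::map_dbl(.data$trajectory, final_belief),
      final_percent = percent_points(.data$final_belief)
    ) |>
    dplyr::rename(archetype = "name") |>
    dplyr::select("archetype", "prior", "likelihood_ratio", "condition",
                  "final_belief", "final_percent", "trajectory")
  class(out) <- c("archetype_comparison", class(out))
  out
}

#' Sweep final beliefs over a grid of priors and bias factors
#'
#' Runs the same evidence stream from every prior under every disconfirming
#' weight and records the final belief, systematizing the single-`w` design
#' into a sensitivity analysis.
#'
#' @param priors Numeric vector of initial beliefs.
#' @param w_values Numeric vector of disconfirming-evidence weights in
#'   `[0, 1]`.
#' @param stream Evidence stream shared by all grid points (vector of
#'   likelihood ratios or a stream tibble).
#' @param threshold Classification threshold; default 0.5.
#' @return A tibble with one row per `(prior, w_disconfirming)` pair and the
#'   resulting `final_belief`.
#' @export
#' @examples
#' sweep_bias(c(0.9, 0.5, 0.1), c(0, 0.5, 1), fixed_stream(10, 0.72))
sweep_bias <- function(priors, w_values, stream, threshold = 0.5) {
  if (length(priors) == 0 || length(w_values) == 0) {
    abort("`priors` and `w_values` must be non-empty.")
  }
  stream <- as_evidence(stream)
  tidyr::expand_grid(prior = priors, w_disconfirming = w_values) |>
    dplyr::mutate(
      final_belief = purrr::map2_dbl(
        .data$prior, .data$w_disconfirming,
        function(p, w) {
          final_belief(run_sequence(p, stream, bias_policy(1, w, threshold)))
        }
      )
    )
}

#' Sensitivity of biased endpoints to the order of mixed evidence
#'
#' Unbiased updating is order-invariant: log likelihood ratios just add. A
#' confirmation-biased updater, in contrast, weighs each trial according to
#' the belief it happens to meet, so the same multiset of trials can end in
#' different places depending on its order. This experiment draws seeded
#' random permutations of a mixed-direction stream, runs the biased policy on
#' each, and reports the spread of final beliefs alongside the single
#' (permutation-invariant) unbiased final.
#'
#' @param stream A mixed-direction evidence stream (must contain trials
#'   favoring each treatment, i.e. likelihood ratios on both sides of 1).
#' @param n_permutations Number of random orderings (at least 2).
#' @param prior Initial belief; default 0.5.
#' @param policy Biased [bias_policy()] applied to every ordering.
#' @param seed Integer seed for drawing permutations.
#' @return An `order_effect` object: a tibble of per-permutation finals (with
#'   the permutation indices recorded for replay), the unbiased final, and
#'   min/max/spread of the biased finals. See [tidy()] and [glance()].
#' @export
#' @examples
#' order_effect_experiment(
#'   mixed_stream(5, 5, 2, seed = 1),
#'   n_permutations = 20,
#'   policy = bias_policy(w_disconfirming = 0.5),
#'   seed = 42
#' )
order_effect_experiment <- function(stream, n_permutations, prior = 0.5,
                                    policy = bias_policy(w_disconfirming = 0.5),
                                    seed = NULL) {
  stream <- as_evidence(stream)
  check_count(n_permutations, "n_permutations", min = 2)
  stopifnot(inherits(policy, "bias_policy"))
  lr <- stream$likelihood_ratio
  if (!any(lr > 1) || !any(lr < 1)) {
    abort("`stream` must contain evidence favoring each treatment (LR on both sides of 1).")
  }

  n <- nrow(stream)
  perms <- with_optional_seed(
    seed,
    lapply(seq_len(n_permutations), function(i) sample.int(n))
  )
  finals <- purrr::map_dbl(perms, function(ord) {
    final_belief(run_sequence(prior, stream[ord, ], policy))
  })
  unbiased_final <- final_belief(run_sequence(prior, stream, unbiased_policy(policy$threshold)))

  structure(
    list(
      permutations = tibble::tibble(
        permutation = seq_len(n_permutations),
        order = perms,
        final_belief = finals
      ),
      unbiased_final = unbiased_final,
      prior = prior,
      policy = policy,
      seed = seed,
      min_final = min(finals),
      max_final = max(finals),
      spread = max(finals) - min(finals)
    ),
    class = "order_effect"
  )
}

#' @export
print.order_effect <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<order_effect> %d permutations, %s\n",
      "  unbiased final (order-invariant): %.6f\n",
      "  biased finals: min %.6f, max %.6f, spread %.3g\n"
    ),
    nrow(x$permutations), format(x$policy),
    x$unbiased_final, x$min_final, x$max_final, x$spread
  ))
  invisible(x)
}

#' @export
tidy.order_effect <- function(x, ...) {
  x$permutations
}

#' @export
glance.order_effect <- function(x, ...) {
  tibble::tibble(
    n_permutations = nrow(x$permutations),
    prior = x$prior,
    unbiased_final = x$unbiased_final,
    min_final = x$min_final,
    max_final = x$max_final,
    spread = x$spread
  )
}

#' Plot an archetype comparison
#'
#' @param object An `archetype_comparison` tibble from
#'   [archetype_comparison()].
#' @param focus Optional archetype name to plot alone (e.g. `"aTSA
#'   Loyalist"`); default plots all archetypes in facets.
#' @param ... Unused.
#' @return A ggplot of belief (0-1) against trial index, biased and unbiased
#'   conditions overlaid.
#' @export
autoplot.archetype_comparison <- function(object, focus = NULL, ...) {
  df <- object |>
    dplyr::mutate(
      points = purrr::map2(.data$trajectory, .data$prior, function(tr, p) {
        tibble::tibble(
          trial = c(0, tr$records$trial_index),
          belief = c(p, tr$records$post_belief)
        )
      })
    ) |>
    dplyr::select("archetype", "condition", "points") |>
    tidyr::unnest("points")
  if (!is.null(focus)) {
    df <- dplyr::filter(df, .data$archetype %in% focus)
    if (nrow(df) == 0) abort(sprintf("unknown archetype `%s`.", focus))
  }
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$trial, y = .data$belief,
                 colour = .data$condition, linetype = .data$condition)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Trial", y = "P(treatment A superior)",
      colour = "Condition", linetype = "Condition",
      title = "Belief updating with and without confirmation bias"
    ) +
    ggplot2::theme_minimal()
  if (is.null(focus) || length(unique(df$archetype)) > 1) {
    p <- p + ggplot2::facet_wrap(~archetype)
  } else {
    p <- p + ggplot2::labs(subtitle = unique(df$archetype))
  }
  p
}
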