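#' Recover the constant per-trial likelihood ratio implied by an endpoint
#'
#' Inverts the unbiased odds-form update: if a belief moved from `prior` to
#' `final` over `n_trials` identical trials, the implied per-trial likelihood
#' ratio is `(odds(final) / odds(prior))^(1 / n_trials)`. Forward-simulating
#' `n_trials` unbiased updates with the implied ratio reproduces `final`.
#'
#' @param prior,final Probabilities that treatment A is superior before and
#'   after the evidence sequence.
#' @param n_trials Number of trials (at least 1).
#' @return An `lr_calibration` object with fields `implied_lr`, `prior`,
#'   `final`, `n_trials`; see also [tidy()].
#' @export
#' @examples
#' calibrate_constant_lr(0.90, 0.25, 10) # implied LR ~ 0.719
calibrate_constant_lr <- function(prior, final, n_trials) {
  prior <- clamp_probability(prior, "prior")
  final <- clamp_probability(final, "final")
  check_count(n_trials, "n_trials")
  implied_lr <- exp((qlogis(final) - qlogis(prior)) / n_trials)
  structure(
    list(implied_lr = implied_lr, prior = prior, final = final,
         n_trials = as.integer(n_trials)),
    class = "lr_calibration"
  )
}

#' @export
print.lr_calibration <- function(x, ...) {
  cat(sprintf(
    "<lr_calibration> prior %.4g -> final %.4g over %d trials: implied LR %.6f\n",
    x$prior, x$final, x$n_trials, x$implied_lr
  ))
  invisible(x)
}

#' @export
tidy.lr_calibration <- function(x, ...) {
  tibble::tibble(
    implied_lr = x$implied_lr, prior = x$prior, final = x$final,
    n_trials = x$n_trials
  )
}

#' Recover the bias factor from a biased endpoint
#'
#' Finds the disconfirming-evidence exponent `w` under which a constant-LR
#' stream carries the belief from `prior` to `observed_final`, with
#' classification against the threshold at every step. The final belief is
#' monotone in `w`, so the solution is found by bisection on `[0, 1]`; each
#' iterate is evaluated by full forward simulation, which handles streams
#' whose trajectory crosses the threshold mid-sequence.
#'
#' @param prior Initial probability that treatment A is superior.
#' @param lr Constant per-trial likelihood ratio.
#' @param n_trials Number of trials.
#' @param observed_final The biased endpoint to invert.
#' @param threshold Classification threshold; default 0.5.
#' @param tol Convergence tolerance on the final belief; default 1e-9.
#' @param max_iter Maximum bisection iterations; default 200.
#' @return The bias factor `w` in `[0, 1]`.
#' @export
#' @examples
#' solve_bias_factor(0.90, 0.72, 10, observed_final = 0.6352297)
solve_bias_factor <- function(prior, lr, n_trials, observed_final,
                              threshold = 0.5, tol = 1e-9, max_iter = 200) {
  prior <- clamp_probability(prior, "prior")
  observed_final <- clamp_probability(observed_final, "observed_final")
  check_lr(lr, "lr")
  check_count(n_trials, "n_trials")

  final_at <- function(w) {
    final_belief(run_sequence(
      prior, fixed_stream(n_trials, lr),
      bias_policy(w_confirming = 1, w_disconfirming = w, threshold = threshold)
    ))
  }

  f0 <- final_at(0)
  f1 <- final_at(1)
  lo_val <- min(f0, f1)
  hi_val <- max(f0, f1)
  if (observed_final < lo_val - tol || observed_final > hi_val + tol) {
    abort(sprintf(
      "no bias factor in [0, 1] attains final %.6g: attainable range is [%.6g, %.6g].",
      observed_final, lo_val, hi_val
    ))
  }
  if (abs(f1 - observed_final) <= tol) return(1)
  if (abs(f0 - observed_final) <= tol) return(0)

  lo <- 0
  hi <- 1
  increasing <- f1 > f0
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- final_at(mid)
    # require the bracket itself to be tight: near-flat stretches of the
    # final-belief curve would otherwise stop the search too early
    if (abs(fm - observed_final) <= tol && (hi - lo) <= 1e-9) return(mid)
    if ((fm < observed_final) == increasing) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Diagnose whether a set of endpoints shares one constant likelihood ratio
#'
#' Calibrates each `(prior, final, n_trials)` row to its implied per-trial
#' likelihood ratio and reports the largest pairwise spread. When a single
#' constant LR generated all the endpoints the spread is zero up to rounding;
#' a spread above `tolerance` flags the endpoints as mutually inconsistent
#' under any one constant LR — which is exactly the situation with the three
#' canonical archetype endpoints (implied LRs of roughly 0.72, 0.68 and
#' 0.80), and why the archetype comparison uses per-archetype constants.
#'
#' @param endpoints A data frame with columns `name`, `prior`, `final`, and
#'   `n_trials`.
#' @param tolerance Maximum pairwise implied-LR spread considered consistent;
#'   default 0.01.
#' @return An `lr_consistency` object: per-row calibrations (a tibble), the
#'   max pairwise spread, the tolerance, and a `consistent` flag.
#' @export
#' @examples
#' implied_lr_report(tibble::tibble(
#'   name = c("Loyalist", "Neutral", "Advocate"),
#'   prior = c(0.90, 0.50, 0.10),
#'   final = c(0.25, 0.020, 0.012),
#'   n_trials = 10
#' ))
implied_lr_report <- function(endpoints, tolerance = 0.01) {
  stopifnot(is.data.frame(endpoints), nrow(endpoints) >= 1)
  needed <- c("name", "prior", "final", "n_trials")
  missing <- setdiff(needed, names(endpoints))
  if (length(missing) > 0) {
    abort(sprintf("`endpoints` lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  results <- purrr::pmap_dfr(
    endpoints[needed],
    function(name, prior, final, n_trials) {
      dplyr::bind_cols(
        tibble::tibble(name = name),
        tidy(calibrate_constant_lr(prior, final, n_trials))
      )
    }
  )
  spread <- max(results$implied_lr) - min(results$implied_lr)
  structure(
    list(
      results = results,
      max_pairwise_lr_discrepancy = spread,
      tolerance = tolerance,
      consistent = spread <= tolerance
    ),
    class = "lr_consistency"
  )
}

#' @export
print.lr_consistency <- function(x, ...) {
  cat(sprintf(
    "<lr_consistency> %d endpoint(s); max implied-LR spread %.4g (tolerance %.4g): %s\n",
    nrow(x$results), x$max_pairwise_lr_discrepancy, x$tolerance,
    if (x$consistent) "consistent with one constant LR" else "NOT consistent with one constant LR"
  ))
  print(x$results)
  invisible(x)
}

#' @export
tidy.lr_consistency <- function(x, ...) {
  x$results
}

#' @export
glance.lr_consistency <- function(x, ...) {
  tibble::tibble(
    n_endpoints = nrow(x$results),
    max_pairwise_lr_discrepancy = x$max_pairwise_lr_discrepancy,
    tolerance = x$tolerance,
    consistent = x$consistent
  )
}
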