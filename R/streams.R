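#' Evidence streams with constant or mixed likelihood ratios
#'
#' `fixed_stream()` builds the canonical constant-effect stream: `n` trials,
#' each carrying the same likelihood ratio, emulating a sequence of
#' randomized trials whose effect size is held constant. `mixed_stream()`
#' builds a stream with trials favoring each treatment at a common strength:
#' A-favoring trials carry `lr_magnitude` expressed as its above-1 form and
#' B-favoring trials its reciprocal, so the evidence is symmetric by
#' construction; the order is shuffled reproducibly under `seed`.
#'
#' @param n Number of trials (at least 1).
#' @param lr Likelihood ratio shared by every trial (A over B; values below 1
#'   favor treatment B).
#' @return A tibble with columns `trial_id`, `likelihood_ratio` (and, for
#'   mixed streams, `favors`).
#' @export
#' @examples
#' fixed_stream(10, 0.72)         # ten B-favoring trials
#' mixed_stream(5, 5, 2, seed = 1) # five trials each way, strength 2
fixed_stream <- function(n, lr) {
  check_count(n, "n")
  check_lr(lr, "lr")
  stopifnot(length(lr) == 1)
  tibble::tibble(trial_id = seq_len(n), likelihood_ratio = rep(as.numeric(lr), n))
}

#' @rdname fixed_stream
#' @param n_favoring_a,n_favoring_b Number of trials favoring treatment A
#'   (likelihood ratio above 1) and treatment B (below 1); not both zero.
#' @param lr_magnitude Common evidence strength; reciprocals are treated as
#'   the same magnitude, so 2 and 0.5 give identical streams.
#' @param seed Integer seed for the reproducible shuffle; `NULL` uses the
#'   current RNG state.
#' @export
mixed_stream <- function(n_favoring_a, n_favoring_b, lr_magnitude, seed = NULL) {
  check_count(n_favoring_a, "n_favoring_a", min = 0)
  check_count(n_favoring_b, "n_favoring_b", min = 0)
  check_lr(lr_magnitude, "lr_magnitude")
  n <- n_favoring_a + n_favoring_b
  if (n == 0) abort("`n_favoring_a` and `n_favoring_b` must not both be zero.")
  lr_a <- if (lr_magnitude >= 1) lr_magnitude else 1 / lr_magnitude
  values <- c(rep(lr_a, n_favoring_a), rep(1 / lr_a, n_favoring_b))
  ord <- with_optional_seed(seed, sample.int(n))
  tibble::tibble(
    trial_id = seq_len(n),
    likelihood_ratio = values[ord],
    favors = ifelse(values[ord] > 1, "A", ifelse(values[ord] < 1, "B", "neutral"))
  )
}

check_count <- function(n, what, min = 1) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n != as.integer(n) || n < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
  invisible(n)
}

with_optional_seed <- function(seed, expr) {
  expr <- substitute(expr)
  if (is.null(seed)) {
    eval(expr, parent.frame())
  } else {
    withr::with_seed(as.integer(seed), eval(expr, parent.frame()))
  }
}

#' Two-arm binomial trial design
#'
#' Specifies a generative model for a comparative trial under two point
#' hypotheses: if A is truly superior (`HA`) each arm's per-patient success
#' probability is taken from `rates_ha`; if B is truly superior (`HB`), from
#' `rates_hb`. Together with an observed outcome this yields a likelihood
#' ratio via the product of the two arms' binomial point masses under each
#' hypothesis.
#'
#' @param n_per_arm Patients per arm (at least 1).
#' @param rates_ha,rates_hb Length-2 numeric vectors `c(p_arm_A, p_arm_B)`
#'   of success probabilities under each hypothesis, each in `[0, 1]`.
#' @return An object of class `trial_design`.
#' @export
#' @examples
#' d <- trial_design(50, rates_ha = c(0.7, 0.5), rates_hb = c(0.5, 0.7))
#' out <- simulate_trial(d, "HB", seed = 1)
#' trial_likelihood_ratio(d, out)
trial_design <- function(n_per_arm, rates_ha, rates_hb) {
  check_count(n_per_arm, "n_per_arm")
  for (r in list(rates_ha = rates_ha, rates_hb = rates_hb)) {
    if (!is.numeric(r) || length(r) != 2) {
      abort("`rates_ha` and `rates_hb` must be length-2 numeric vectors.")
    }
  }
  check_probability(rates_ha, "rates_ha")
  check_probability(rates_hb, "rates_hb")
  structure(
    list(
      n_per_arm = as.integer(n_per_arm),
      rates_ha = as.numeric(rates_ha),
      rates_hb = as.numeric(rates_hb)
    ),
    class = "trial_design"
  )
}

#' @rdname trial_design
#' @param design A [trial_design()].
#' @param true_hypothesis `"HA"` or `"HB"`: which hypothesis generates the
#'   data.
#' @param seed Optional integer seed for reproducible draws.
#' @return `simulate_trial()`: a list with integer counts `successes_a` and
#'   `successes_b`.
#' @export
simulate_trial <- function(design, true_hypothesis = c("HA", "HB"), seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  true_hypothesis <- match.arg(true_hypothesis)
  rates <- if (true_hypothesis == "HA") design$rates_ha else design$rates_hb
  draws <- with_optional_seed(seed, rbinom(2, design$n_per_arm, rates))
  list(successes_a = draws[1], successes_b = draws[2])
}

#' @rdname trial_design
#' @param outcome A list with `successes_a` and `successes_b`, as returned by
#'   `simulate_trial()`.
#' @return `trial_likelihood_ratio()`: the likelihood ratio
#'   P(outcome | HA) / P(outcome | HB), computed in log space.
#' @export
trial_likelihood_ratio <- function(design, outcome) {
  stopifnot(inherits(design, "trial_design"))
  sa <- outcome$successes_a
  sb <- outcome$successes_b
  n <- design$n_per_arm
  if (is.null(sa) || is.null(sb) || sa < 0 || sb < 0 || sa > n || sb > n) {
    abort("`outcome` counts must lie in [0, n_per_arm].")
  }
  log_ha <- dbinom(sa, n, design$rates_ha[1], log = TRUE) +
    dbinom(sb, n, design$rates_ha[2], log = TRUE)
  log_hb <- dbinom(sa, n, design$rates_hb[1], log = TRUE) +
    dbinom(sb, n, design$rates_hb[2], log = TRUE)
  log_lr <- log_ha - log_hb
  if (is.nan(log_lr)) {
    abort(sprintf(
      "likelihood ratio undefined for outcome (%d, %d): zero probability under both hypotheses.",
      sa, sb
    ))
  }
  if (!is.finite(log_lr)) {
    abort(sprintf(
      "likelihood ratio degenerate for outcome (%d, %d): zero probability under one hypothesis.",
      sa, sb
    ))
  }
  exp(log_lr)
}

#' Generate an evidence stream from simulated binomial trials
#'
#' Repeatedly simulates a two-arm trial under the stated true hypothesis and
#' converts each outcome to a likelihood-ratio evidence item. This is a
#' generative extension of the constant-effect stream: effect sizes vary
#' trial to trial with sampling noise.
#'
#' @param design A [trial_design()].
#' @param n_trials Number of trials to simulate.
#' @param true_hypothesis `"HA"` or `"HB"`.
#' @param seed Optional integer seed.
#' @return A tibble with `trial_id`, `successes_a`, `successes_b`,
#'   `likelihood_ratio`.
#' @export
binomial_stream <- function(design, n_trials, true_hypothesis = c("HA", "HB"),
                            seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  check_count(n_trials, "n_trials")
  true_hypothesis <- match.arg(true_hypothesis)
  rates <- if (true_hypothesis == "HA") design$rates_ha else design$rates_hb
  draws <- with_optional_seed(seed, matrix(
    rbinom(2 * n_trials, design$n_per_arm, rep(rates, n_trials)),
    ncol = 2, byrow = TRUE
  ))
  lr <- purrr::map_dbl(seq_len(n_trials), function(i) {
    trial_likelihood_ratio(
      design,
      list(successes_a = draws[i, 1], successes_b = draws[i, 2])
    )
  })
  tibble::tibble(
    trial_id = seq_len(n_trials),
    successes_a = draws[, 1],
    successes_b = draws[, 2],
    likelihood_ratio = lr
  )
}
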