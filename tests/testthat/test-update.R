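test_that("evidence classification depends on which side of threshold the belief sits", {
  expect_identical(classify_evidence(0.90, 0.72), "disconfirming")
  expect_identical(classify_evidence(0.10, 0.72), "confirming")
  expect_identical(classify_evidence(0.90, 1.4), "confirming")
  expect_identical(classify_evidence(0.10, 1.4), "disconfirming")
  expect_identical(classify_evidence(0.90, 1), "neutral")
  # equipoise counts as favoring A, so B-favoring evidence is disconfirming
  expect_identical(classify_evidence(0.50, 0.72), "disconfirming")
  expect_identical(classify_evidence(0.50, 1.4), "confirming")
  # non-default threshold
  expect_identical(classify_evidence(0.60, 0.72, threshold = 0.7), "confirming")
})

test_that("apply_update matches direct odds arithmetic", {
  # 9 * 0.72 = 6.48; 6.48 / 7.48
  expect_equal(apply_update(0.9, 0.72, 1), 6.48 / 7.48, tolerance = 1e-9)
  # 9 * sqrt(0.72) = 7.636753...; discounted update
  o <- 9 * 0.72^0.5
  expect_equal(apply_update(0.9, 0.72, 0.5), o / (1 + o), tolerance = 1e-9)
  # neutral evidence and zero weight leave the belief unchanged
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(apply_update(p, 1, 0.7), p, tolerance = 1e-12)
    expect_equal(apply_update(p, 0.3, 0), p, tolerance = 1e-12)
  }
  expect_error(apply_update(0.9, 0.72, 1.2), "weight")
  expect_error(apply_update(0.9, -1, 1), "positive")
})

test_that("run_sequence chains posteriors and records every trial", {
  traj <- run_sequence(0.9, fixed_stream(10, 0.72))
  rec <- tidy(traj)
  expect_identical(nrow(rec), 10L)
  expect_identical(rec$trial_index, 1:10)
  expect_identical(rec$pre_belief[1], 0.9)
  expect_identical(rec$pre_belief[-1], rec$post_belief[-10])
  # the belief crosses 0.5 after trial 7, so the last three B-favoring
  # trials confirm the now-B-leaning belief
  expect_identical(rec$classification,
                   c(rep("disconfirming", 7), rep("confirming", 3)))
  expect_identical(unique(rec$weight_applied), 1)
  # each record is one odds-form update of its own pre-belief
  expect_equal(
    rec$post_belief,
    purrr::pmap_dbl(rec, function(pre_belief, likelihood_ratio, weight_applied, ...) {
      apply_update(pre_belief, likelihood_ratio, weight_applied)
    }),
    tolerance = 1e-12
  )
  expect_equal(final_belief(traj), 0.2520297, tolerance = 1e-6)
  expect_error(run_sequence(0.9, numeric(0)), "at least one")
})

test_that("unbiased updating equals the closed-form log-odds cumulative sum bit for bit", {
  set.seed(11)
  for (i in 1:20) {
    p0 <- runif(1, 0.05, 0.95)
    lrs <- exp(runif(12, -1, 1))
    traj <- run_sequence(p0, lrs, bias_policy(1, 1))
    expect_identical(tidy(traj)$post_belief, closed_form_beliefs(p0, lrs))
    expect_equal(final_belief(traj), odds_product_final(p0, lrs), tolerance = 1e-12)
  }
})

test_that("unbiased finals are order-invariant; biased finals are not", {
  set.seed(7)
  lrs <- c(rep(0.5, 5), rep(2, 5))
  base <- final_belief(run_sequence(0.5, lrs))
  for (i in 1:10) {
    perm <- sample(lrs)
    expect_equal(final_belief(run_sequence(0.5, perm)), base, tolerance = 1e-9)
  }
  pol <- bias_policy(w_disconfirming = 0.5)
  f_b_first <- final_belief(run_sequence(0.5, c(rep(0.5, 5), rep(2, 5)), pol))
  f_a_first <- final_belief(run_sequence(0.5, c(rep(2, 5), rep(0.5, 5)), pol))
  expect_gt(abs(f_a_first - f_b_first), 1e-6)
})

test_that("half-weight bias dilates time: 2k biased trials equal k unbiased", {
  pol <- bias_policy(w_disconfirming = 0.5)
  for (k in c(1, 3, 5)) {
    biased <- final_belief(run_sequence(0.95, fixed_stream(2 * k, 0.9), pol))
    unbiased <- final_belief(run_sequence(0.95, fixed_stream(k, 0.9)))
    expect_equal(biased, unbiased, tolerance = 1e-9)
  }
})

test_that("B-favoring evidence strictly lowers belief and bias only slows the fall", {
  traj_u <- run_sequence(0.9, fixed_stream(10, 0.9))
  traj_b <- run_sequence(0.9, fixed_stream(10, 0.9), bias_policy(w_disconfirming = 0.5))
  pu <- c(0.9, tidy(traj_u)$post_belief)
  pb <- c(0.9, tidy(traj_b)$post_belief)
  expect_true(all(diff(pu) < 0))
  expect_true(all(diff(pb) < 0))
  # dominance: every biased point sits at or above its unbiased counterpart
  expect_true(all(pb >= pu))
})

test_that("updating with a ratio and then its reciprocal restores the prior", {
  for (p0 in c(0.1, 0.5, 0.9)) {
    for (c0 in c(0.3, 0.72, 2.5)) {
      expect_equal(final_belief(run_sequence(p0, c(c0, 1 / c0))), p0,
                   tolerance = 1e-12)
    }
  }
})

test_that("w_disconfirming = 0 makes an all-disconfirming stream inert", {
  traj <- run_sequence(0.9, fixed_stream(10, 0.72), bias_policy(1, 0))
  post <- tidy(traj)$post_belief
  expect_identical(length(unique(post)), 1L) # log-odds state never moves
  expect_equal(post, rep(0.9, 10), tolerance = 1e-12)
  expect_identical(unique(tidy(traj)$classification), "disconfirming")
})

test_that("trajectory summaries and plots expose the endpoint", {
  traj <- run_sequence(0.5, fixed_stream(10, 0.678), bias_policy(w_disconfirming = 0.5))
  g <- glance(traj)
  expect_identical(g$n_trials, 10L)
  expect_identical(g$n_disconfirming, 1L)
  expect_identical(g$n_confirming, 9L)
  expect_identical(g$final_percent, 2.4)
  p <- autoplot(traj)
  expect_s3_class(p, "ggplot")
})
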