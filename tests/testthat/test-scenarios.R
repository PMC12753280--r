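test_that("the canonical archetypes are fixed", {
  a <- archetypes()
  expect_identical(nrow(a), 3L)
  expect_identical(a$name, c("aTSA Loyalist", "Neutral Thinker", "rTSA Advocate"))
  expect_identical(a$prior, c(0.90, 0.50, 0.10))
  expect_true(all(a$prior > 0 & a$prior < 1))
})

test_that("archetype comparison reproduces the canonical endpoints", {
  cmp <- archetype_comparison()
  expect_identical(nrow(cmp), 6L)
  ep <- function(arch, cond) {
    cmp$final_percent[cmp$archetype == arch & cmp$condition == cond]
  }
  expect_identical(ep("aTSA Loyalist", "unbiased"), 25)
  expect_identical(ep("aTSA Loyalist", "biased"), 64)
  expect_identical(ep("Neutral Thinker", "unbiased"), 2.0)
  expect_identical(ep("rTSA Advocate", "unbiased"), 1.2)
  expect_identical(ep("rTSA Advocate", "biased"), 1.2)
  # 39-point bias effect for the Loyalist
  expect_identical(ep("aTSA Loyalist", "biased") - ep("aTSA Loyalist", "unbiased"), 39)

  # the Advocate's trajectory is bias-invariant at full precision
  adv <- cmp[cmp$archetype == "rTSA Advocate", ]
  expect_identical(tidy(adv$trajectory[[1]])$post_belief,
                   tidy(adv$trajectory[[2]])$post_belief)

  # deterministic: a second run is identical
  expect_identical(cmp$final_belief, archetype_comparison()$final_belief)

  expect_error(archetype_comparison(lr = c("aTSA Loyalist" = 0.72)),
               "Neutral Thinker")
})

test_that("biased endpoints dominate unbiased ones when the prior resists B-favoring evidence", {
  cmp <- archetype_comparison()
  wide <- tidyr::pivot_wider(
    cmp[, c("archetype", "condition", "final_belief")],
    names_from = "condition", values_from = "final_belief"
  )
  expect_true(all(wide$biased >= wide$unbiased))
})

test_that("the neutral archetype's first trial is its only disconfirming one", {
  cmp <- archetype_comparison()
  tr <- cmp$trajectory[cmp$archetype == "Neutral Thinker" & cmp$condition == "biased"][[1]]
  rec <- tidy(tr)
  expect_identical(rec$classification,
                   c("disconfirming", rep("confirming", 9)))
  expect_identical(rec$weight_applied, c(0.5, rep(1, 9)))
  # one discounted trial barely slows the fall: endpoint near the unbiased one
  expect_identical(glance(tr)$final_percent, 2.4)
})

test_that("sweep_bias covers the full grid with exact anchor columns", {
  stream <- fixed_stream(10, 0.72)
  sw <- sweep_bias(c(0.9, 0.5, 0.1), c(0, 0.5, 1), stream)
  expect_identical(nrow(sw), 9L)
  expect_identical(nrow(dplyr::distinct(sw[, c("prior", "w_disconfirming")])), 9L)

  # w = 1 column equals unbiased finals
  for (p in c(0.9, 0.5, 0.1)) {
    expect_identical(
      sw$final_belief[sw$prior == p & sw$w_disconfirming == 1],
      final_belief(run_sequence(p, stream))
    )
  }
  # w = 0 with an all-disconfirming stream leaves the prior in place
  expect_equal(sw$final_belief[sw$prior == 0.9 & sw$w_disconfirming == 0], 0.9,
               tolerance = 1e-12)
  # finals increase toward the prior's side as w falls (all-disconfirming rows)
  row9 <- sw$final_belief[sw$prior == 0.9]
  expect_true(all(diff(row9[order(c(0, 0.5, 1))]) < 0))
  expect_error(sweep_bias(numeric(0), 1, stream), "non-empty")
})

test_that("evidence order moves biased endpoints but never unbiased ones", {
  stream <- mixed_stream(5, 5, 2, seed = 4)
  exp <- order_effect_experiment(
    stream, n_permutations = 25, prior = 0.5,
    policy = bias_policy(w_disconfirming = 0.5), seed = 11
  )
  # unbiased final is permutation-invariant and cancels back to the prior
  expect_equal(exp$unbiased_final, 0.5, tolerance = 1e-9)
  expect_gt(exp$spread, 1e-6)
  expect_identical(nrow(tidy(exp)), 25L)
  # permutation indices are recorded for replay
  replay <- tidy(exp)$order[[3]]
  expect_identical(
    tidy(exp)$final_belief[3],
    final_belief(run_sequence(0.5, stream[replay, ],
                              bias_policy(w_disconfirming = 0.5)))
  )
  # deterministic under the same seed
  exp2 <- order_effect_experiment(
    stream, n_permutations = 25, prior = 0.5,
    policy = bias_policy(w_disconfirming = 0.5), seed = 11
  )
  expect_identical(tidy(exp)$final_belief, tidy(exp2)$final_belief)
  expect_error(
    order_effect_experiment(fixed_stream(10, 0.72), 10, seed = 1),
    "both sides"
  )
})

test_that("exhaustive enumeration of a small mixed stream shows distinct biased finals", {
  # independent oracle for order dependence: all 4!/(2!2!)-distinct orderings
  # of a 2-vs-2 reciprocal stream
  lrs <- c(2, 2, 0.5, 0.5)
  perms <- unique(combinat_perms(lrs))
  finals <- vapply(perms, function(v) {
    final_belief(run_sequence(0.5, v, bias_policy(w_disconfirming = 0.5)))
  }, numeric(1))
  expect_gt(max(finals) - min(finals), 1e-6)
  # while the unbiased finals all collapse to the prior
  finals_u <- vapply(perms, function(v) {
    final_belief(run_sequence(0.5, v))
  }, numeric(1))
  expect_equal(finals_u, rep(0.5, length(finals_u)), tolerance = 1e-9)
})

test_that("comparison plots build for all archetypes and for a focus archetype", {
  cmp <- archetype_comparison()
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(autoplot(cmp, focus = "aTSA Loyalist"), "ggplot")
  expect_error(autoplot(cmp, focus = "nobody"), "unknown archetype")
})
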