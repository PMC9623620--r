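test_that("ROC curve endpoints, monotonicity and perfect separation", {
  r <- roc_curve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  # cutoff 2 separates perfectly: (fpr, tpr) = (0, 1)
  i <- which(r$cutoffs == 2)
  expect_equal(c(r$fpr[i], r$tpr[i]), c(0, 1))
  expect_equal(roc_auc(r), 1)
  # single-class labels are rejected
  expect_error(roc_curve(1:4, c(TRUE, TRUE, TRUE, TRUE)), "ROC undefined")
})

test_that("trapezoidal AUC equals the pairwise-probability oracle", {
  # the spec-level identity, exercised across random tied instances
  for (seed in 1:25) {
    inst <- random_roc_instance(seed)
    for (orient in c("lower_is_positive", "higher_is_positive")) {
      r <- roc_curve(inst$values, inst$labels, orient, check_direction = FALSE)
      expect_equal(roc_auc(r), auc_pairwise_oracle(inst$values, inst$labels, orient),
                   tolerance = 1e-12, label = sprintf("seed %d / %s", seed, orient))
    }
  }
  # flipping orientation complements the AUC
  inst <- random_roc_instance(99)
  a_lo <- roc_auc(roc_curve(inst$values, inst$labels, "lower_is_positive",
                            check_direction = FALSE))
  a_hi <- roc_auc(roc_curve(inst$values, inst$labels, "higher_is_positive",
                            check_direction = FALSE))
  expect_equal(a_lo + a_hi, 1, tolerance = 1e-12)
  # labels independent of values: all observations tied
  r <- roc_curve(rep(7, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                 check_direction = FALSE)
  expect_equal(roc_auc(r), 0.5)
  # alternating instance, hand-enumerated: pos {2,4} vs neg {1,3} has a
  # single concordant pair under lower_is_positive
  expect_equal(roc_auc(roc_curve(1:4, c(FALSE, TRUE, FALSE, TRUE),
                                 check_direction = FALSE)), 0.25)
})

test_that("AUC agrees with the pROC reference implementation", {
  for (seed in c(3, 14, 15)) {
    inst <- random_roc_instance(seed)
    r <- roc_curve(inst$values, inst$labels, "lower_is_positive",
                   check_direction = FALSE)
    ref <- pROC::roc(response = inst$labels, predictor = inst$values,
                     direction = ">", quiet = TRUE, levels = c(FALSE, TRUE))
    expect_equal(roc_auc(r), as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})

test_that("the orientation guard rejects a curve below chance", {
  expect_error(roc_curve(1:4, c(FALSE, FALSE, TRUE, TRUE), "lower_is_positive"),
               "orientation")
  expect_silent(roc_curve(1:4, c(FALSE, FALSE, TRUE, TRUE), "lower_is_positive",
                          check_direction = FALSE))
})

test_that("Youden selection maximizes J with deterministic tie-breaking", {
  for (seed in 26:45) {
    inst <- random_roc_instance(seed)
    r <- roc_curve(inst$values, inst$labels, check_direction = FALSE)
    best <- cutoff_youden(r)
    j_all <- r$tpr + (1 - r$fpr) - 1
    expect_gte(best$j + 1e-12, max(j_all))
    expect_equal(best$j, youden_j(best$se, best$sp))
    expect_equal(best$dist_sq, (1 - best$se)^2 + (1 - best$sp)^2)
    expect_equal(best$dist, sqrt(best$dist_sq))
  }
  # tie on J: pos {1, 3}, neg {2, 4}; cutoffs 1 and 3 both give J = 0.5,
  # the corner distance prefers the higher-sensitivity point only when it is
  # smaller, so the (0.5, 1) vs (1, 0.5) tie resolves by distance equality
  # then higher se -> cutoff 3
  r <- roc_curve(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE),
                 check_direction = FALSE)
  best <- cutoff_youden(r)
  expect_equal(best$cutoff, 3)
  expect_equal(best$se, 1)
  # degenerate single-cutoff curve
  r1 <- roc_curve(c(5, 5), c(TRUE, FALSE), check_direction = FALSE)
  expect_equal(cutoff_youden(r1)$cutoff, 5)
})

test_that("performance at a pre-specified cutoff counts correctly", {
  r <- roc_curve(c(5, 9, 11, 15), c(TRUE, TRUE, FALSE, FALSE))
  p <- performance_at(r, 10)
  expect_equal(c(p$se, p$sp), c(1, 1))
  expect_equal(p$j, 1); expect_equal(p$dist, 0)
  # cutoff below / above every value
  expect_equal(unlist(performance_at(r, 4)[c("se", "sp")]),
               c(se = 0, sp = 1))
  expect_equal(unlist(performance_at(r, 16)[c("se", "sp")]),
               c(se = 1, sp = 0))
  # point estimates always inside their exact intervals
  for (cut in c(4, 7, 10, 12, 16)) {
    q <- performance_at(r, cut)
    expect_true(q$se >= q$se_lo && q$se <= q$se_hi)
    expect_true(q$sp >= q$sp_lo && q$sp <= q$sp_hi)
  }
})

test_that("constrained rule-in/rule-out thresholds behave at the edges", {
  # perfectly separating test: empty grey zone
  r <- roc_curve(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE))
  cc <- constrained_cutoffs(r, 0.95, 0.95)
  expect_equal(cc$rule_in, cc$rule_out)
  expect_equal(cc$rule_in, 2)
  # min_sp = 0 releases the constraint entirely: full-sensitivity rule-in
  # (the smallest cutoff calling every positive, by the max-sp tie-break)
  inst <- random_roc_instance(7)
  r2 <- roc_curve(inst$values, inst$labels, check_direction = FALSE)
  cc2 <- constrained_cutoffs(r2, min_sp = 0, min_se = 0.5)
  expect_equal(cc2$rule_in_se, 1)
  expect_equal(cc2$rule_in, max(inst$values[inst$labels]))
  # unsatisfiable side is NA with an explanation
  r3 <- roc_curve(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                  check_direction = FALSE)
  expect_message(cc3 <- constrained_cutoffs(r3, min_sp = 0.95, min_se = 0.95),
                 "no cutoff")
  expect_true(is.na(cc3$rule_in))
})

test_that("raising the specificity constraint never raises rule-in sensitivity", {
  for (seed in 46:60) {
    inst <- random_roc_instance(seed)
    r <- roc_curve(inst$values, inst$labels, check_direction = FALSE)
    prev <- Inf
    for (msp in c(0.5, 0.7, 0.9, 0.99)) {
      cc <- suppressMessages(constrained_cutoffs(r, min_sp = msp, min_se = 0.5))
      se <- if (is.na(cc$rule_in)) 0 else cc$rule_in_se
      expect_lte(se, prev + 1e-12)
      prev <- se
    }
  }
})
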