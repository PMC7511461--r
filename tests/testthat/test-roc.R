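test_that("degenerate classifiers give the textbook AUC values", {
  # perfect separation
  rc <- roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(rc$auc, 1)
  expect_identical(rc$auc_ci[2], 1)
  # uninformative score: every comparison is a tie
  expect_identical(roc_curve(c(3, 3, 3, 3), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  # hand-enumerated: 5 concordant of 6 event/non-event pairs
  rc2 <- roc_curve(c(3, 5, 1, 2, 4), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rc2$auc, 5 / 6)
})

test_that("input validation rejects unusable data", {
  expect_error(roc_curve(1:4, rep(TRUE, 4)), class = "laceroc_undefined_auc")
  expect_error(roc_curve(1:4, rep(FALSE, 4)), class = "laceroc_undefined_auc")
  expect_error(roc_curve(1:4, c(TRUE, FALSE)), class = "laceroc_validation_error")
  expect_error(roc_curve(c(1, NA, 3), c(TRUE, FALSE, TRUE)),
               class = "laceroc_validation_error")
})

test_that("concordance AUC equals the brute-force all-pairs oracle exactly", {
  withr::with_seed(314, {
    for (i in 1:25) {
      inst <- rand_instance(sample(10:200, 1))
      rc <- roc_curve(inst$scores, inst$outcomes)
      expect_identical(rc$auc, auc_bruteforce(inst$scores, inst$outcomes))
      # and the trapezoidal area under the step polygon agrees to 1e-12
      expect_lt(abs(rc$auc - auc_trapezoid(rc$curve)), 1e-12)
    }
  })
})

test_that("step curves are monotone with the correct endpoints", {
  withr::with_seed(2718, {
    for (i in 1:20) {
      inst <- rand_instance(sample(20:500, 1))
      cv <- roc_curve(inst$scores, inst$outcomes)$curve
      expect_true(all(diff(cv$sensitivity) <= 0))
      expect_true(all(diff(cv$specificity) >= 0))
      expect_identical(cv$sensitivity[1], 1)          # t = min score
      expect_identical(cv$specificity[1], 0)
      expect_identical(cv$sensitivity[nrow(cv)], 0)   # t = max score + 1
      expect_identical(cv$specificity[nrow(cv)], 1)
      expect_identical(cv$threshold,
                       seq(min(inst$scores), max(inst$scores) + 1))
    }
  })
})

test_that("AUC and DeLong variance agree with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(99, {
    for (i in 1:5) {
      inst <- rand_instance(300)
      rc <- roc_curve(inst$scores, inst$outcomes, ci_method = "delong")
      ref <- pROC::roc(response = inst$outcomes, predictor = inst$scores,
                       direction = "<", quiet = TRUE)
      expect_equal(rc$auc, as.numeric(pROC::auc(ref)))
      expect_equal(rc$auc_se, sqrt(pROC::var(ref)), tolerance = 1e-8)
    }
  })
})

test_that("Hanley-McNeil intervals cover the true AUC in at least 90% of cohorts", {
  mu <- 1                                   # binormal separation
  true_auc <- pnorm(mu / sqrt(2))
  withr::with_seed(1234, {
    hits <- vapply(1:1000, function(i) {
      scores <- c(rnorm(250, mu), rnorm(250, 0))
      outcomes <- rep(c(TRUE, FALSE), each = 250)
      ci <- roc_curve(scores, outcomes)$auc_ci
      ci[1] <= true_auc && true_auc <= ci[2]
    }, logical(1))
  })
  expect_gte(mean(hits), 0.90)
})

test_that("likelihood ratios follow their defining identities", {
  # uninformative point
  lr <- lr_from_rates(0.5, 0.5)
  expect_identical(lr$lr_pos, 1)
  expect_identical(lr$lr_neg, 1)
  # boundary: perfect specificity flags an infinite LR+ rather than erroring
  lr2 <- lr_from_rates(0.5, 1)
  expect_identical(lr2$lr_pos, Inf)
  expect_identical(lr2$lr_neg, 0.5)
  # identities on a random sweep
  withr::with_seed(7, {
    se <- runif(50); sp <- runif(50, 0.01, 0.99)
    lr3 <- lr_from_rates(se, sp)
    expect_equal(lr3$lr_pos, se / (1 - sp))
    expect_equal(lr3$lr_neg, (1 - se) / sp)
  })
})

test_that("likelihood ratios at fractional thresholds use the interpolated curve", {
  rc <- roc_curve(c(9, 9, 10, 10, 10), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # at t = 9.5: sens midway between 1 (t=9) and 0 (t=10); spec midway 0 -> 0
  lr <- likelihood_ratios(rc, 9.5)
  expect_equal(lr$sensitivity, 0.5)
  expect_equal(lr$specificity, 0)
  expect_error(likelihood_ratios(rc, 30), class = "laceroc_validation_error")
})

test_that("tidy, glance and autoplot expose the curve", {
  inst <- withr::with_seed(1, rand_instance(100))
  rc <- roc_curve(inst$scores, inst$outcomes)
  expect_named(tidy(rc), c("threshold", "sensitivity", "specificity"))
  g <- glance(rc)
  expect_identical(nrow(g), 1L)
  expect_true(g$auc_ci_lower <= g$auc && g$auc <= g$auc_ci_upper)
  expect_s3_class(ggplot2::autoplot(rc), "ggplot")
})
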