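toy_curve <- function(threshold, sensitivity, specificity) {
  tibble::tibble(threshold = threshold, sensitivity = sensitivity,
                 specificity = specificity)
}

test_that("an exact grid intersection is returned as-is", {
  cv <- toy_curve(7:11, c(1, 0.9, 0.6, 0.3, 0), c(0, 0.2, 0.6, 0.9, 1))
  tg <- two_graph(cv)
  expect_identical(tg$theta0, 9)
  expect_identical(tg$equal_value, 0.6)
})

test_that("crossings between grid points are linearly interpolated", {
  # symmetric lines crossing midway between 9 and 10
  cv <- toy_curve(c(9, 10), c(1, 0.4), c(0.4, 1))
  expect_identical(two_graph(cv)$theta0, 9.5)
  # asymmetric: sens 0.8->0.2, spec 0.1->0.8; crossing at 9 + 0.7/1.3
  cv2 <- toy_curve(c(9, 10), c(0.8, 0.2), c(0.1, 0.8))
  expect_equal(two_graph(cv2)$theta0, 9 + 0.7 / 1.3)
})

test_that("a flat equality segment returns its midpoint", {
  cv <- toy_curve(8:11, c(1, 0.5, 0.5, 0), c(0, 0.5, 0.5, 1))
  expect_identical(two_graph(cv)$theta0, 9.5)
})

test_that("curves that never cross raise a no-crossing error", {
  cv <- toy_curve(8:10, c(0.1, 0.05, 0), c(0.5, 0.8, 1))
  expect_error(two_graph(cv), class = "laceroc_no_crossing")
  expect_error(two_graph(toy_curve(1, 1, 0), level = 0.4),
               class = "laceroc_validation_error")
})

test_that("sensitivity equals specificity at theta0 on generated cohorts", {
  withr::with_seed(161, {
    for (i in 1:15) {
      inst <- rand_instance(sample(50:2000, 1))
      rc <- roc_curve(inst$scores, inst$outcomes)
      tg <- two_graph(rc)
      at <- with(rc$curve, list(
        s = approx(threshold, sensitivity, tg$theta0)$y,
        p = approx(threshold, specificity, tg$theta0)$y
      ))
      expect_lt(abs(at$s - at$p), 1e-9)
      expect_equal(tg$equal_value, at$s, tolerance = 1e-12)
      # theta0 within the score range
      expect_gte(tg$theta0, min(rc$curve$threshold))
      expect_lte(tg$theta0, max(rc$curve$threshold))
    }
  })
})

test_that("the intermediate range brackets theta0 and narrows with the level", {
  co <- simulate_cohort(cohort_config(n_per_band = rep(1500, 5), seed = 21))
  rc <- roc_curve(add_lace(co), lace, died_within_6mo)
  tg95 <- two_graph(rc, level = 0.95)
  tg90 <- two_graph(rc, level = 0.90)
  expect_false(any(tg95$clipped))
  expect_lte(tg95$ir_lower, tg95$theta0)
  expect_gte(tg95$ir_upper, tg95$theta0)
  # IR_90% is inside IR_95%
  expect_gte(tg90$ir_lower, tg95$ir_lower)
  expect_lte(tg90$ir_upper, tg95$ir_upper)
  expect_identical(tg90$theta0, tg95$theta0)
})

test_that("unattainable intermediate limits are clipped and flagged", {
  # specificity is above the level over the whole range
  cv <- toy_curve(8:10, c(1, 0.5, 0), c(0.96, 0.97, 1))
  tg <- two_graph(cv, level = 0.95)
  expect_true(tg$clipped[["upper"]])
  expect_equal(tg$ir_upper, 8)
})

test_that("theta0 recovers a planted latent crossing at large n", {
  # rounded-normal scores: events N(12, 2), non-events N(7, 2). The latent
  # step curves P(round(X) >= t) cross where (t - 0.5 - 12)/2 = -(t - 0.5 - 7)/2,
  # i.e. at t* = (12 + 7)/2 + 0.5 = 10.
  withr::with_seed(424242, {
    n <- 50000
    scores <- round(c(rnorm(n / 2, 12, 2), rnorm(n / 2, 7, 2)))
    outcomes <- rep(c(TRUE, FALSE), each = n / 2)
    tg <- two_graph(roc_curve(scores, outcomes))
    expect_lt(abs(tg$theta0 - 10), 0.25)
  })
})

test_that("half-point thresholds act as the next integer on integer scores", {
  scores <- rep(0:19, times = 5)
  outcomes <- rep(c(TRUE, FALSE), length.out = length(scores))
  a <- threshold_impact(scores, outcomes, 11.5, 12)
  expect_identical(a$events_flagged_a, a$events_flagged_b)
  expect_identical(a$false_positive_rate_a, a$false_positive_rate_b)
})

test_that("two-graph tidy output and plot are well formed", {
  co <- simulate_cohort(cohort_config(n_per_band = rep(500, 5), seed = 8))
  tg <- two_graph(roc_curve(add_lace(co), lace, died_within_6mo))
  td <- tidy(tg)
  expect_identical(nrow(td), 1L)
  expect_named(td, c("theta0", "equal_value", "ir_lower", "ir_upper", "level",
                     "clipped_lower", "clipped_upper"))
  expect_s3_class(ggplot2::autoplot(tg), "ggplot")
})
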