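small_config <- function(...) {
  cohort_config(n_per_band = c(40, 30, 30, 30, 40), seed = 101, ...)
}

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_per_band = c(0, 1, 1, 1, 1)), "n_per_band",
               class = "laceroc_validation_error")
  expect_error(cohort_config(death_30d_rate = c(0.9, 0.1, 0.1, 0.1, 0.1)),
               "death_30d_rate", class = "laceroc_validation_error")
  expect_error(cohort_config(discrimination_slope = -1),
               "discrimination_slope", class = "laceroc_validation_error")
  expect_error(cohort_config(discrimination_slope = c(1, 2)),
               "discrimination_slope", class = "laceroc_validation_error")
  expect_error(cohort_config(death_6mo_rate = c(0.1, 0.1)), "death_6mo_rate",
               class = "laceroc_validation_error")
})

test_that("band counts are exact, ages in range, and the default cohort has 32,270 episodes", {
  co <- simulate_cohort(small_config())
  expect_identical(nrow(co), 170L)
  counts <- table(assign_band(co$age_years))
  expect_identical(as.integer(counts), c(40L, 30L, 30L, 30L, 40L))
  expect_true(all(co$age_years >= 18 & co$age_years <= 107))

  full <- simulate_cohort(cohort_config(seed = 1))
  expect_identical(nrow(full), 32270L)
  expect_identical(as.integer(table(assign_band(full$age_years))),
                   c(8403L, 4304L, 4739L, 6068L, 8756L))
})

test_that("cohorts are byte-identical given the same config and seed", {
  cfg <- small_config()
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_false(identical(simulate_cohort(cfg, seed = 1),
                         simulate_cohort(cfg, seed = 2)))
})

test_that("zero rates produce zero events and 30-day deaths nest in 6-month deaths", {
  cfg <- cohort_config(n_per_band = rep(200, 5), discrimination_slope = 0,
                       death_6mo_rate = rep(0, 5), death_30d_rate = rep(0, 5),
                       frequent_readmit_rate = rep(0, 5), seed = 5)
  co <- simulate_cohort(cfg)
  expect_identical(sum(co$died_within_6mo), 0L)
  expect_identical(sum(co$died_within_30d), 0L)
  expect_identical(sum(co$readmissions_28d), 0L)

  co2 <- simulate_cohort(small_config())
  expect_true(all(co2$died_within_6mo[co2$died_within_30d]))
})

test_that("marginal rates are binomially calibrated at slope zero", {
  cfg <- cohort_config(n_per_band = c(10, 10, 10, 10, 50000),
                       discrimination_slope = 0, seed = 33)
  co <- simulate_cohort(cfg)
  top <- co[assign_band(co$age_years) == ">=80", ]
  ci <- qbinom(c(0.005, 0.995), 50000, 0.156) / 50000
  rate <- mean(top$died_within_6mo)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("intercept calibration matches its closed form and a grid oracle", {
  # no score effect: closed form logit(r)
  expect_identical(calibrate_intercept(0.05, scores = 0:19, slope = 0),
                   qlogis(0.05))

  scores <- rep(c(2, 5, 9, 14), times = c(10, 30, 40, 20))
  a <- calibrate_intercept(0.05, scores, slope = 0.5)
  achieved <- mean(plogis(a + 0.5 * (scores - mean(scores))))
  expect_lt(abs(achieved - 0.05), 1e-6)

  # grid-search oracle: the root lies where the grid objective is minimal
  grid <- seq(-10, 2, by = 1e-4)
  obj <- vapply(grid, function(g) {
    abs(mean(plogis(g + 0.5 * (scores - mean(scores)))) - 0.05)
  }, numeric(1))
  expect_lt(abs(a - grid[which.min(obj)]), 1e-3)

  # monotone in the target rate
  expect_gt(calibrate_intercept(0.10, scores, 0.5),
            calibrate_intercept(0.05, scores, 0.5))

  expect_error(calibrate_intercept(0, scores, 0.5),
               class = "laceroc_no_finite_intercept")
  expect_error(calibrate_intercept(1, scores, 0.5),
               class = "laceroc_no_finite_intercept")
})

test_that("per-band intercepts target each band's rate", {
  cfg <- small_config()
  samples <- replicate(5, sample(0:19, 500, replace = TRUE), simplify = FALSE)
  a <- calibrate_intercepts(cfg, samples, outcome = "death_6mo")
  expect_named(a, age_bands()$label)
  achieved <- vapply(seq_along(a), function(b) {
    s <- samples[[b]]
    mean(plogis(a[b] + cfg$discrimination_slope[b] * (s - mean(s))))
  }, numeric(1))
  expect_true(all(abs(achieved - cfg$death_6mo_rate) < 1e-6))

  cfg0 <- cohort_config(n_per_band = rep(10, 5),
                        death_6mo_rate = c(0, 0.1, 0.1, 0.1, 0.1),
                        death_30d_rate = rep(0, 5))
  expect_true(is.na(calibrate_intercepts(cfg0, samples, "death_6mo")[1]))
})

test_that("discrimination slope controls the score-outcome AUC", {
  aucs <- vapply(c(0, 0.2, 0.5, 1.0), function(s) {
    cfg <- cohort_config(n_per_band = c(1, 1, 1, 1, 20000),
                         discrimination_slope = s, seed = 77)
    co <- add_lace(simulate_cohort(cfg))
    top <- co[co$age_years >= 80, ]
    roc_curve(top$lace, top$died_within_6mo)$auc
  }, numeric(1))
  expect_lte(aucs[1], 0.51)
  expect_true(all(diff(aucs) > -0.005))
  expect_gt(aucs[4], 0.75)
})

test_that("emitted ICD-10 codes round-trip to the generated Charlson index", {
  co <- simulate_cohort(small_config(emit_icd10 = TRUE))
  rescored <- add_charlson(dplyr::select(co, -"charlson_index"))
  expect_identical(rescored$charlson_index, co$charlson_index)
})

test_that("readmission counts agree with the frequent-readmission flag construction", {
  co <- simulate_cohort(cohort_config(n_per_band = rep(2000, 5), seed = 9))
  # counts of >= 2 occur at roughly the configured band rates
  rate <- mean(co$readmissions_28d[co$age_years >= 80] >= 2)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.067) / 2000
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("cohort CSVs round-trip and invalid tables fail with row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- simulate_cohort(small_config(emit_icd10 = TRUE))
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co))

  bad <- co
  bad$age_years[3] <- 12
  bad$died_within_30d[7] <- TRUE
  bad$died_within_6mo[7] <- FALSE
  err <- tryCatch(validate_episodes(bad), error = identity)
  expect_s3_class(err, "laceroc_validation_error")
  expect_match(conditionMessage(err), "rows 3")
  expect_match(conditionMessage(err), "rows 7")

  expect_error(validate_episodes(co[, 1:4]), "missing columns",
               class = "laceroc_validation_error")
})
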