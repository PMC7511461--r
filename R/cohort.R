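#' Default age bands
#'
#' The five-band age stratification used throughout: adults 18-49.9 combined
#' as the youngest category, decades 50-59.9, 60-69.9 and 70-79.9, and all
#' patients aged 80 or over combined as the oldest. Bands are
#' lower-inclusive, upper-exclusive and partition `[18, Inf)`.
#'
#' @return A tibble with columns `label`, `lower`, `upper`.
#' @examples
#' age_bands()
#' @export
age_bands <- function() {
  tibble(
    label = c("18-49.9", "50-59.9", "60-69.9", "70-79.9", ">=80"),
    lower = c(18, 50, 60, 70, 80),
    upper = c(50, 60, 70, 80, Inf)
  )
}

#' Synthetic cohort configuration
#'
#' Builds and validates the configuration for [simulate_cohort()]. The
#' defaults reproduce the structure of a two-year NHS unplanned-admission
#' cohort of 32,270 alive-discharge episodes: the five age-band sizes and
#' the band-specific rates of death within 6 months (0.5/2.0/4.8/7.7/15.6%),
#' death within 30 days (0.2/0.7/1.8/2.9/6.0%) and frequent readmission,
#' i.e. two or more readmissions within 28 days (1.0/1.5/2.4/3.3/6.7%).
#'
#' Outcomes are drawn from a logistic model on the LACE score,
#' `logit P = a_band + slope * (lace - mean band lace)`, with `a_band`
#' calibrated by [calibrate_intercept()] so each band's marginal rate equals
#' its target. `discrimination_slope` (log-odds per LACE point) therefore
#' controls the score's discrimination (AUC) without disturbing the rates;
#' it may be a scalar or one value per band.
#'
#' @param n_per_band Positive integer episode counts, one per band.
#' @param death_6mo_rate,death_30d_rate,frequent_readmit_rate Per-band
#'   outcome probabilities in `[0, 1]`; the 30-day rate may not exceed the
#'   6-month rate in any band.
#' @param discrimination_slope Non-negative log-odds increase per LACE
#'   point; scalar or one value per band.
#' @param seed Integer seed making the cohort reproducible.
#' @param los_mean Mean of the geometric length-of-stay distribution (days).
#' @param p_emergent Probability an admission is emergent (the cohort is
#'   unplanned admissions, so the default is 1).
#' @param ed_mean Mean of the Poisson prior-ED-visit count, truncated at
#'   `ed_max`.
#' @param ed_max Truncation point for ED visit counts.
#' @param charlson_probs Categorical distribution of the Charlson index over
#'   `0:10` (normalized internally).
#' @param emit_icd10 If `TRUE`, each episode carries an ICD-10 code set that
#'   realizes its Charlson index (see [charlson_codes_for()]), exercising
#'   the comorbidity coding path end to end; otherwise `icd10_codes` is
#'   empty.
#' @param e_dialect E-component dialect used when scoring, see
#'   [lace_score()].
#' @param bands Age-band table, see [age_bands()].
#' @param age_max Oldest age generated (the top band is truncated here).
#' @return A validated list of class `cohort_config`.
#' @examples
#' cohort_config(n_per_band = rep(100, 5), seed = 42)
#' @export
cohort_config <- function(n_per_band = c(8403, 4304, 4739, 6068, 8756),
                          death_6mo_rate = c(0.005, 0.020, 0.048, 0.077, 0.156),
                          death_30d_rate = c(0.002, 0.007, 0.018, 0.029, 0.060),
                          frequent_readmit_rate = c(0.010, 0.015, 0.024, 0.033, 0.067),
                          discrimination_slope = 0.4,
                          seed = 20170401L,
                          los_mean = 4,
                          p_emergent = 1,
                          ed_mean = 1,
                          ed_max = 10,
                          charlson_probs = c(0.45, 0.18, 0.12, 0.08, 0.06,
                                             0.04, 0.03, 0.02, 0.01, 0.005,
                                             0.005),
                          emit_icd10 = FALSE,
                          e_dialect = c("count_capped", "binary"),
                          bands = age_bands(),
                          age_max = 107) {
  nb <- nrow(bands)
  check_number(n_per_band, "n_per_band", lower = 1, integerish = TRUE, len = nb)
  check_number(death_6mo_rate, "death_6mo_rate", lower = 0, upper = 1, len = nb)
  check_number(death_30d_rate, "death_30d_rate", lower = 0, upper = 1, len = nb)
  check_number(frequent_readmit_rate, "frequent_readmit_rate",
               lower = 0, upper = 1, len = nb)
  if (any(death_30d_rate > death_6mo_rate)) {
    stop_bad_arg("death_30d_rate",
                 "may not exceed `death_6mo_rate` in any band.")
  }
  if (!length(discrimination_slope) %in% c(1L, nb)) {
    stop_bad_arg("discrimination_slope",
                 sprintf("must be a scalar or one value per band (%d).", nb))
  }
  check_number(discrimination_slope, "discrimination_slope", lower = 0)
  check_number(seed, "seed", integerish = TRUE, len = 1)
  check_number(los_mean, "los_mean", lower = 0)
  check_number(p_emergent, "p_emergent", lower = 0, upper = 1)
  check_number(ed_mean, "ed_mean", lower = 0)
  check_number(ed_max, "ed_max", lower = 0, integerish = TRUE)
  check_number(charlson_probs, "charlson_probs", lower = 0, len = 11)
  if (sum(charlson_probs) <= 0) {
    stop_bad_arg("charlson_probs", "must have positive total mass.")
  }
  check_flag(emit_icd10, "emit_icd10")
  e_dialect <- match.arg(e_dialect)

  structure(list(
    n_per_band = as.integer(n_per_band),
    death_6mo_rate = death_6mo_rate,
    death_30d_rate = death_30d_rate,
    frequent_readmit_rate = frequent_readmit_rate,
    discrimination_slope = rep_len(discrimination_slope, nb),
    seed = as.integer(seed),
    los_mean = los_mean, p_emergent = p_emergent,
    ed_mean = ed_mean, ed_max = as.integer(ed_max),
    charlson_probs = charlson_probs / sum(charlson_probs),
    emit_icd10 = emit_icd10, e_dialect = e_dialect,
    bands = bands, age_max = age_max
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", sum(x$n_per_band), "episodes in",
      length(x$n_per_band), "age bands; slope =",
      paste(unique(x$discrimination_slope), collapse = "/"),
      "; seed =", x$seed, "\n")
  invisible(x)
}

#' Calibrate a logistic intercept to a target marginal rate
#'
#' Finds the intercept `a` such that the mean of
#' `plogis(a + slope * (scores - mean(scores)))` over a score sample equals
#' the target rate. The mean logistic probability is strictly increasing in
#' `a`, so the root is unique; it is located by monotone root-finding to an
#' absolute rate tolerance of 1e-9 (well inside 1e-6). When `slope = 0` the
#' closed form `qlogis(rate)` is returned exactly.
#'
#' @param target_rate Target marginal probability, strictly inside (0, 1).
#'   A rate of exactly 0 or 1 has no finite intercept and is an error
#'   (condition class `laceroc_no_finite_intercept`); callers handle those
#'   cases as constant outcomes.
#' @param scores Non-empty numeric score sample.
#' @param slope Non-negative slope (log-odds per score point).
#' @return The intercept, a length-one numeric.
#' @examples
#' calibrate_intercept(0.05, scores = 0:19, slope = 0.5)
#' calibrate_intercept(0.05, scores = 0:19, slope = 0)  # qlogis(0.05)
#' @export
calibrate_intercept <- function(target_rate, scores, slope) {
  check_number(target_rate, "target_rate", lower = 0, upper = 1, len = 1)
  check_number(slope, "slope", lower = 0, len = 1)
  if (length(scores) == 0) {
    stop_bad_arg("scores", "must be a non-empty score sample.")
  }
  if (target_rate <= 0 || target_rate >= 1) {
    abort("No finite intercept exists for a target rate of 0 or 1.",
          class = "laceroc_no_finite_intercept")
  }
  if (slope == 0) return(qlogis(target_rate))
  centred <- scores - mean(scores)
  f <- function(a) mean(plogis(a + slope * centred)) - target_rate
  uniroot(f, interval = c(-40, 40), extendInt = "upX", tol = 1e-12)$root
}

#' Per-band calibrated intercepts
#'
#' Vectorized companion to [calibrate_intercept()]: one intercept per age
#' band for a chosen outcome, given a per-band sample of LACE scores.
#'
#' @param config A [cohort_config()].
#' @param score_samples List of non-empty numeric score samples, one per
#'   band.
#' @param outcome Which outcome's band rates to target.
#' @return Named numeric vector of intercepts (band labels as names);
#'   `NA` where the band's target rate is 0 or 1 (constant outcome).
#' @export
calibrate_intercepts <- function(config, score_samples,
                                 outcome = c("death_6mo", "death_30d",
                                             "frequent_readmit")) {
  outcome <- match.arg(outcome)
  rates <- config[[paste0(outcome, "_rate")]]
  nb <- nrow(config$bands)
  if (!is.list(score_samples) || length(score_samples) != nb ||
      any(lengths(score_samples) == 0)) {
    stop_bad_arg("score_samples", "must be one non-empty sample per band.")
  }
  out <- vapply(seq_len(nb), function(b) {
    if (rates[b] <= 0 || rates[b] >= 1) return(NA_real_)
    calibrate_intercept(rates[b], score_samples[[b]],
                        config$discrimination_slope[b])
  }, numeric(1))
  names(out) <- config$bands$label
  out
}

# Poisson mean such that P(X >= 2) equals the frequent-readmission rate
readmit_lambda <- function(rate) {
  if (rate <= 0) return(0)
  uniroot(function(l) ppois(1, l, lower.tail = FALSE) - rate,
          interval = c(1e-12, 100), tol = 1e-12)$root
}

# draw readmission counts consistent with the frequent flag: >= 2 when
# flagged, <= 1 otherwise, both from the band-calibrated Poisson conditional
draw_readmissions <- function(frequent, lambda) {
  n <- length(frequent)
  counts <- integer(n)
  if (lambda <= 0) return(counts)
  lo <- ppois(1, lambda)                      # P(X <= 1)
  if (any(!frequent)) {
    p0 <- dpois(0, lambda) / lo
    counts[!frequent] <- rbinom(sum(!frequent), 1L, 1 - p0)
  }
  if (any(frequent)) {
    u <- runif(sum(frequent), lo, 1)
    counts[frequent] <- qpois(u, lambda)
  }
  counts
}

draw_outcome <- function(rate, scores, slope) {
  n <- length(scores)
  if (rate <= 0) return(rep(FALSE, n))
  if (rate >= 1) return(rep(TRUE, n))
  a <- calibrate_intercept(rate, scores, slope)
  p <- plogis(a + slope * (scores - mean(scores)))
  runif(n) < p
}

#' Generate a synthetic cohort of discharge episodes
#'
#' Draws a cohort of alive-discharge unplanned-admission episodes matching
#' the configured age-band sizes and outcome rates. Within each band, ages
#' are uniform over the band interval (the oldest band is truncated at
#' `age_max`); length of stay is geometric, ED visits truncated Poisson and
#' the Charlson index categorical, per the configuration. Each episode's
#' LACE score is computed and the three outcomes are drawn from the
#' calibrated logistic model described in [cohort_config()]. Death within
#' 30 days is a thinning of death within 6 months (conditional probability
#' equal to the band's rate ratio), so the 30-day deaths are always a subset
#' of the 6-month deaths. Readmission counts are drawn from a band-calibrated
#' Poisson conditional on the frequent-readmission flag, so that
#' `readmissions_28d >= 2` coincides with the modelled flag and the marginal
#' frequency of two or more readmissions matches the band rate.
#'
#' The same config and seed always produce the identical cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Seed to use; defaults to the one in `config`.
#' @return A tibble with one row per episode: `episode_id`, `age_years`,
#'   `acuity_emergent`, `length_of_stay_days`, `icd10_codes`
#'   (semicolon-separated, possibly empty), `charlson_index`,
#'   `ed_visits_6mo`, `died_within_30d`, `died_within_6mo`,
#'   `readmissions_28d`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_band = rep(200, 5), seed = 7))
#' dplyr::count(cohort, died_within_6mo)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(seed, {
    bands <- config$bands
    parts <- lapply(seq_len(nrow(bands)), function(b) {
      n <- config$n_per_band[b]
      upper <- min(bands$upper[b], config$age_max)
      age <- runif(n, bands$lower[b], upper)
      los <- rgeom(n, 1 / (1 + config$los_mean))
      emergent <- runif(n) < config$p_emergent
      charlson <- sample(0:10, n, replace = TRUE, prob = config$charlson_probs)
      ed <- pmin(rpois(n, config$ed_mean), config$ed_max)
      score <- lace_score(los, emergent, charlson, ed,
                          e_dialect = config$e_dialect)$lace

      slope <- config$discrimination_slope[b]
      died6 <- draw_outcome(config$death_6mo_rate[b], score, slope)
      died30 <- rep(FALSE, n)
      if (config$death_6mo_rate[b] > 0 && any(died6)) {
        p30 <- config$death_30d_rate[b] / config$death_6mo_rate[b]
        died30[died6] <- runif(sum(died6)) < p30
      }
      frequent <- draw_outcome(config$frequent_readmit_rate[b], score, slope)
      readmits <- draw_readmissions(frequent,
                                    readmit_lambda(config$frequent_readmit_rate[b]))

      tibble(
        age_years = age,
        acuity_emergent = emergent,
        length_of_stay_days = as.integer(los),
        charlson_index = as.integer(charlson),
        ed_visits_6mo = as.integer(ed),
        died_within_30d = died30,
        died_within_6mo = died6,
        readmissions_28d = as.integer(readmits)
      )
    })
    out <- dplyr::bind_rows(parts)
    out$episode_id <- sprintf("E%06d", seq_len(nrow(out)))
    out$icd10_codes <- ""
    if (config$emit_icd10) {
      codes_by_index <- vapply(0:10, function(i) {
        paste(charlson_codes_for(i), collapse = ";")
      }, character(1))
      out$icd10_codes <- codes_by_index[out$charlson_index + 1L]
    }
    dplyr::select(out, "episode_id", "age_years", "acuity_emergent",
                  "length_of_stay_days", "icd10_codes", "charlson_index",
                  "ed_visits_6mo", "died_within_30d", "died_within_6mo",
                  "readmissions_28d")
  })
}

#' Validate an episode table
#'
#' Checks the episode CSV schema: required columns, value ranges (adult
#' ages, non-negative counts) and the consistency rule that a death within
#' 30 days is also a death within 6 months. Violations are reported with
#' the offending row numbers.
#'
#' @param data Episode data frame.
#' @return `data`, invisibly, when valid; otherwise an error listing every
#'   failed check with row numbers.
#' @export
validate_episodes <- function(data) {
  required <- c("age_years", "acuity_emergent", "length_of_stay_days",
                "ed_visits_6mo", "died_within_30d", "died_within_6mo",
                "readmissions_28d")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(paste("Episode table is missing columns:",
                paste(missing, collapse = ", ")),
          class = "laceroc_validation_error")
  }
  problems <- character()
  bad <- function(rows, what) {
    if (length(rows)) {
      sprintf("%s (rows %s)", what,
              paste(head(rows, 5), collapse = ", ")) |>
        c(problems)
    } else problems
  }
  problems <- bad(which(data$age_years < 18 | is.na(data$age_years)),
                  "age_years below 18 or missing")
  problems <- bad(which(data$length_of_stay_days < 0), "negative length of stay")
  problems <- bad(which(data$ed_visits_6mo < 0), "negative ED visit count")
  problems <- bad(which(data$readmissions_28d < 0), "negative readmission count")
  problems <- bad(which(data$died_within_30d & !data$died_within_6mo),
                  "died within 30 days but not within 6 months")
  if (length(problems)) {
    abort(paste0("Episode table failed validation:\n- ",
                 paste(problems, collapse = "\n- ")),
          class = "laceroc_validation_error")
  }
  invisible(data)
}

#' Write / read an episode cohort CSV
#'
#' The on-disk format is one row per episode with the columns documented in
#' [simulate_cohort()]; `icd10_codes` is a semicolon-delimited string (empty
#' when no diagnoses are carried). [read_cohort()] validates the table on
#' load via [validate_episodes()].
#'
#' @param data Episode data frame.
#' @param path File path.
#' @return `write_cohort()` returns `data` invisibly; `read_cohort()`
#'   returns a validated tibble.
#' @export
write_cohort <- function(data, path) {
  if (is.list(data[["icd10_codes"]])) {
    data$icd10_codes <- vapply(data$icd10_codes, paste, character(1),
                               collapse = ";")
  }
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      episode_id = readr::col_character(),
      icd10_codes = readr::col_character(),
      acuity_emergent = readr::col_logical(),
      died_within_30d = readr::col_logical(),
      died_within_6mo = readr::col_logical(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  data$icd10_codes <- dplyr::coalesce(data$icd10_codes, "")
  validate_episodes(data)
  data
}
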