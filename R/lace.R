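#' Length-of-stay scoring bins for the LACE L component
#'
#' The day-count bins of the published LACE index: stays of 0 days score 0,
#' 1/2/3 days score their own value, 4-6 days score 4, 7-13 days score 5 and
#' 14 or more days score 7. Shipped as a data file rather than hard-coded so
#' alternative binnings can be inspected or swapped.
#'
#' @param path Optional replacement CSV with columns `days_min`, `days_max`,
#'   `points`.
#' @return A tibble with one row per bin.
#' @examples
#' lace_los_bins()
#' @export
lace_los_bins <- function(path = NULL) {
  path <- path %||% system.file("extdata", "lace_los_bins.csv",
                                package = "laceroc", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

los_points <- function(days, bins = lace_los_bins()) {
  idx <- findInterval(days, bins$days_min)
  as.integer(bins$points[idx])
}

#' LACE components and total score
#'
#' Computes the four LACE components and the 0-19 total for each episode:
#' L from the length-of-stay bins ([lace_los_bins()], 0-7 points), A = 3 for
#' an emergent (unplanned) admission and 0 otherwise, C from the Charlson
#' comorbidity index via [charlson_lace_subscore()] (0-5 points), and E from
#' the count of emergency-department visits in the prior six months
#' (0-4 points).
#'
#' Two dialects of the E component are supported. The default,
#' `"count_capped"`, scores the visit count capped at 4 (the published LACE
#' definition). `"binary"` scores 0 for no prior visits and 4 for one or
#' more, the literal reading of a two-level "0 or 4" component. Both keep
#' the total within 0-19.
#'
#' @param length_of_stay_days Integer vector of stay lengths in days (>= 0).
#' @param acuity_emergent Logical vector: was the admission emergent?
#' @param charlson_index Integer vector of Charlson comorbidity indices
#'   (>= 0), e.g. from [charlson_flags()] or [add_charlson()].
#' @param ed_visits_6mo Integer vector of prior-6-month ED visit counts
#'   (>= 0).
#' @param e_dialect E-component dialect, `"count_capped"` (default) or
#'   `"binary"`.
#' @return A tibble with integer columns `L`, `A`, `C`, `E` and `lace`
#'   (the total, always in 0-19).
#' @examples
#' lace_score(5, TRUE, 2, 1)           # components 4 + 3 + 2 + 1 = 10
#' lace_score(14, TRUE, 4, 4)          # the maximum attainable score, 19
#' @seealso [add_lace()] for the data-frame verb.
#' @export
lace_score <- function(length_of_stay_days, acuity_emergent, charlson_index,
                       ed_visits_6mo,
                       e_dialect = c("count_capped", "binary")) {
  e_dialect <- match.arg(e_dialect)
  check_number(length_of_stay_days, "length_of_stay_days", lower = 0,
               integerish = TRUE)
  check_flag(acuity_emergent, "acuity_emergent")
  check_number(ed_visits_6mo, "ed_visits_6mo", lower = 0, integerish = TRUE)

  L <- los_points(length_of_stay_days)
  A <- ifelse(acuity_emergent, 3L, 0L)
  C <- charlson_lace_subscore(charlson_index)
  E <- if (e_dialect == "binary") ifelse(ed_visits_6mo >= 1, 4L, 0L)
       else as.integer(pmin(ed_visits_6mo, 4L))
  tibble(L = L, A = as.integer(A), C = C, E = E,
         lace = as.integer(L + A + C + E))
}

#' Append LACE columns to an episode table
#'
#' Data-frame verb: scores every episode and appends the component columns
#' `L`, `A`, `C`, `E` and the total `lace`. Expects the generator/CSV schema
#' columns `length_of_stay_days`, `acuity_emergent`, `ed_visits_6mo` and a
#' `charlson_index` column; if `charlson_index` is absent but `icd10_codes`
#' is present, the Charlson index is computed first via [add_charlson()].
#'
#' @param data Episode data frame.
#' @param e_dialect E-component dialect, see [lace_score()].
#' @param map Charlson coding table, used only when the index must be
#'   derived from ICD-10 codes.
#' @return `data` with `L`, `A`, `C`, `E`, `lace` columns appended (and
#'   `charlson_index` if it had to be derived).
#' @examples
#' simulate_cohort(cohort_config(n_per_band = rep(20, 5), seed = 1)) |>
#'   add_lace()
#' @export
add_lace <- function(data, e_dialect = c("count_capped", "binary"),
                     map = charlson_map()) {
  e_dialect <- match.arg(e_dialect)
  if (is.null(data[["charlson_index"]])) {
    if (is.null(data[["icd10_codes"]])) {
      stop_bad_arg("data", "needs a `charlson_index` or `icd10_codes` column.")
    }
    data <- add_charlson(data, map = map)
  }
  scored <- lace_score(data$length_of_stay_days, data$acuity_emergent,
                       data$charlson_index, data$ed_visits_6mo,
                       e_dialect = e_dialect)
  dplyr::bind_cols(data, scored)
}
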