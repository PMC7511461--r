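#' Derive the study outcomes for each episode
#'
#' Appends the three analysis outcomes as logical columns: `death_6mo` and
#' `death_30d` pass the recorded death indicators through, and
#' `frequent_readmit` is TRUE when the episode was followed by two or more
#' readmissions within 28 days of the index discharge.
#'
#' @param data Episode data frame with `died_within_6mo`, `died_within_30d`
#'   and `readmissions_28d` columns.
#' @return `data` with `death_6mo`, `death_30d`, `frequent_readmit`
#'   appended.
#' @examples
#' tibble::tibble(died_within_6mo = FALSE, died_within_30d = FALSE,
#'                readmissions_28d = 2) |> define_outcomes()
#' @export
define_outcomes <- function(data) {
  check_number(data$readmissions_28d, "readmissions_28d", lower = 0,
               integerish = TRUE)
  dplyr::mutate(data,
                death_6mo = .data$died_within_6mo,
                death_30d = .data$died_within_30d,
                frequent_readmit = .data$readmissions_28d >= 2)
}

#' Assign ages to age bands
#'
#' Maps each age to the band containing it; bands are lower-inclusive,
#' upper-exclusive. Ages below the adult cohort floor of 18 are an error.
#'
#' @param age_years Numeric ages.
#' @param bands Age-band table, see [age_bands()].
#' @return Factor of band labels, levels in band order.
#' @examples
#' assign_band(c(49.9, 50, 107))
#' @export
assign_band <- function(age_years, bands = age_bands()) {
  check_number(age_years, "age_years")
  if (any(age_years < min(bands$lower))) {
    abort(sprintf("Ages below %s are outside the adult cohort.",
                  min(bands$lower)),
          class = "laceroc_out_of_cohort")
  }
  idx <- findInterval(age_years, bands$lower)
  factor(bands$label[idx], levels = bands$label)
}

#' @rdname assign_band
#' @param data Episode data frame with an `age_years` column.
#' @export
add_age_band <- function(data, bands = age_bands()) {
  data$age_band <- assign_band(data$age_years, bands)
  data
}

#' Impact of moving a decision threshold
#'
#' Compares two thresholds on the same score/outcome data: how many events
#' (e.g. deaths) each threshold flags as test-positive under the rule
#' "score >= t", the corresponding percentages of all events captured, the
#' false-positive rate among non-events, and the relative change in flagged
#' events from threshold `threshold_a` to `threshold_b`. On integer scores
#' a half-point threshold such as 11.5 flags exactly the episodes scoring
#' at or above the next integer. Percentages are reported to one decimal.
#'
#' @param x Numeric score vector, or a data frame.
#' @param outcomes Logical event indicator; at least one event is required.
#' @param threshold_a,threshold_b The two thresholds to compare.
#' @param ... Passed between methods.
#' @return One-row tibble: `threshold_a`, `threshold_b`, `events_total`,
#'   `events_flagged_a`, `events_flagged_b`, `pct_flagged_a`,
#'   `pct_flagged_b`, `relative_change_pct`, `false_positive_rate_a`,
#'   `false_positive_rate_b`.
#' @examples
#' scores <- c(rep(12, 8), rep(7, 27), rep(3, 9), rep(2, 300))
#' events <- c(rep(TRUE, 44), rep(FALSE, 300))
#' threshold_impact(scores, events, 10, 5)
#' @export
threshold_impact <- function(x, ...) UseMethod("threshold_impact")

#' @export
threshold_impact.default <- function(x, outcomes, threshold_a, threshold_b,
                                     ...) {
  scores <- x
  check_number(scores, "scores")
  check_flag(outcomes, "outcomes")
  check_number(threshold_a, "threshold_a", len = 1)
  check_number(threshold_b, "threshold_b", len = 1)
  if (length(scores) != length(outcomes)) {
    stop_bad_arg("outcomes", "must have the same length as the scores.")
  }
  if (!any(outcomes)) {
    abort("Threshold impact is undefined without any events.",
          class = "laceroc_no_events")
  }
  events_total <- sum(outcomes)
  n_neg <- sum(!outcomes)
  fa <- sum(outcomes & scores >= threshold_a)
  fb <- sum(outcomes & scores >= threshold_b)
  fpa <- if (n_neg > 0) sum(!outcomes & scores >= threshold_a) / n_neg else NA_real_
  fpb <- if (n_neg > 0) sum(!outcomes & scores >= threshold_b) / n_neg else NA_real_
  tibble(
    threshold_a = threshold_a, threshold_b = threshold_b,
    events_total = events_total,
    events_flagged_a = fa, events_flagged_b = fb,
    pct_flagged_a = round(100 * fa / events_total, 1),
    pct_flagged_b = round(100 * fb / events_total, 1),
    relative_change_pct = if (fa > 0) round(100 * (fa - fb) / fa, 1)
                          else NA_real_,
    false_positive_rate_a = fpa, false_positive_rate_b = fpb
  )
}

#' @rdname threshold_impact
#' @param score,outcome For the data-frame method: unquoted column names.
#' @export
threshold_impact.data.frame <- function(x, score, outcome, threshold_a,
                                        threshold_b, ...) {
  s <- eval_tidy(enquo(score), x)
  o <- eval_tidy(enquo(outcome), x)
  threshold_impact(s, o, threshold_a, threshold_b, ...)
}

study_cell <- function(scores, events, ir_level, ci_method, conf_level,
                       reference_threshold, alt_threshold, label, outcome) {
  empty <- tibble(
    stratum = label, outcome = outcome, n = length(scores),
    n_events = sum(events), auc = NA_real_, auc_se = NA_real_,
    auc_ci_lower = NA_real_, auc_ci_upper = NA_real_, p_value = NA_real_,
    theta0 = NA_real_, ir_lower = NA_real_, ir_upper = NA_real_,
    equal_value = NA_real_, lr_pos = NA_real_, lr_neg = NA_real_,
    roc = list(NULL), twograph = list(NULL), impact = list(NULL)
  )
  if (sum(events) == 0 || sum(!events) == 0) {
    warn(sprintf("Stratum '%s', outcome '%s': %s; cell reported as undefined.",
                 label, outcome,
                 if (sum(events) == 0) "no events" else "no non-events"))
    return(empty)
  }
  rc <- roc_curve(scores, events, ci_method = ci_method,
                  conf_level = conf_level)
  tg <- tryCatch(two_graph(rc, level = ir_level),
                 laceroc_no_crossing = function(e) NULL)
  if (is.null(tg)) {
    warn(sprintf("Stratum '%s', outcome '%s': no sensitivity/specificity crossing; threshold cell undefined.",
                 label, outcome))
    out <- empty
    out$roc <- list(rc)
    out[c("auc", "auc_se", "auc_ci_lower", "auc_ci_upper", "p_value")] <-
      as.list(c(rc$auc, rc$auc_se, rc$auc_ci, rc$p_value))
    return(out)
  }
  lr <- likelihood_ratios(rc, tg$theta0)
  impacts <- dplyr::bind_rows(
    threshold_impact(scores, events, reference_threshold, tg$theta0),
    if (!is.null(alt_threshold)) {
      threshold_impact(scores, events, reference_threshold, alt_threshold)
    }
  )
  tibble(
    stratum = label, outcome = outcome, n = length(scores),
    n_events = sum(events),
    auc = rc$auc, auc_se = rc$auc_se,
    auc_ci_lower = rc$auc_ci[1], auc_ci_upper = rc$auc_ci[2],
    p_value = rc$p_value,
    theta0 = tg$theta0, ir_lower = tg$ir_lower, ir_upper = tg$ir_upper,
    equal_value = tg$equal_value,
    lr_pos = lr$lr_pos, lr_neg = lr$lr_neg,
    roc = list(rc), twograph = list(tg), impact = list(impacts)
  )
}

#' Run the full age-stratified LACE study
#'
#' Orchestrates the analysis end to end: validates the episode table,
#' scores LACE (deriving the Charlson index from ICD-10 codes when needed),
#' derives the outcomes, assigns age bands, and for every outcome in every
#' stratum (all patients plus each band) estimates the ROC curve with AUC
#' and confidence interval, derives the two-graph equal-error threshold and
#' intermediate range, evaluates likelihood ratios at the stratum's own
#' threshold, and summarises the impact of using the conventional reference
#' threshold versus the age-specific one (for the oldest band, also versus
#' `elderly_alt_threshold`). Strata with no events (or no non-events) for
#' an outcome are reported as undefined with a warning and the run
#' continues.
#'
#' @param data Episode data frame (see [simulate_cohort()] for the schema);
#'   a pre-computed `lace` column is used if present.
#' @param bands Age-band table, see [age_bands()].
#' @param ir_level Accuracy level of the intermediate range (default 0.95;
#'   0.90 gives the narrower variant).
#' @param ci_method AUC confidence-interval method, see [roc_curve()].
#' @param conf_level Confidence level for AUC intervals.
#' @param reference_threshold The conventional high-risk cutoff compared
#'   against each stratum's derived threshold (default 10).
#' @param elderly_alt_threshold Additional comparison threshold for the
#'   oldest band (default 11.5); `NULL` to skip.
#' @param e_dialect E-component dialect used if LACE must be scored.
#' @param map Charlson coding table, used only if the index must be derived.
#' @return An object of class `lace_study` whose `results` tibble has one
#'   row per outcome and stratum with summary columns plus `roc`,
#'   `twograph` and `impact` list-columns. Use [tidy()] for the flat
#'   summary, [glance()] for totals and [report_study()] for a
#'   publication-style rounded table.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_band = rep(400, 5), seed = 3))
#' study <- run_study(cohort)
#' tidy(study)
#' @export
run_study <- function(data, bands = age_bands(), ir_level = 0.95,
                      ci_method = c("hanley-mcneil", "delong"),
                      conf_level = 0.95, reference_threshold = 10,
                      elderly_alt_threshold = 11.5,
                      e_dialect = c("count_capped", "binary"),
                      map = charlson_map()) {
  ci_method <- match.arg(ci_method)
  e_dialect <- match.arg(e_dialect)
  validate_episodes(data)
  if (is.null(data[["lace"]])) {
    data <- add_lace(data, e_dialect = e_dialect, map = map)
  }
  data <- data |> define_outcomes() |> add_age_band(bands)

  outcomes <- c("death_6mo", "death_30d", "frequent_readmit")
  strata <- c("all", levels(data$age_band))
  top_band <- bands$label[nrow(bands)]

  grid <- tidyr::expand_grid(outcome = outcomes, stratum = strata)
  results <- purrr::pmap(grid, function(outcome, stratum) {
    rows <- if (stratum == "all") rep(TRUE, nrow(data))
            else data$age_band == stratum
    study_cell(
      data$lace[rows], data[[outcome]][rows],
      ir_level = ir_level, ci_method = ci_method, conf_level = conf_level,
      reference_threshold = reference_threshold,
      alt_threshold = if (stratum == top_band) elderly_alt_threshold,
      label = stratum, outcome = outcome
    )
  }) |> dplyr::bind_rows()

  structure(
    list(results = results, n_total = nrow(data), bands = bands,
         ir_level = ir_level, ci_method = ci_method,
         conf_level = conf_level,
         reference_threshold = reference_threshold,
         elderly_alt_threshold = elderly_alt_threshold),
    class = "lace_study"
  )
}

#' @export
print.lace_study <- function(x, ...) {
  cat(sprintf("<lace_study> %d episodes; %d analysis cells (IR level %d%%, %s CI)\n",
              x$n_total, nrow(x$results), round(100 * x$ir_level),
              x$ci_method))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname run_study
#' @param x A `lace_study` object.
#' @param ... Unused.
#' @method tidy lace_study
#' @export
tidy.lace_study <- function(x, ...) {
  dplyr::select(x$results, -"roc", -"twograph", -"impact")
}

#' @rdname run_study
#' @method glance lace_study
#' @export
glance.lace_study <- function(x, ...) {
  tibble(n = x$n_total, n_cells = nrow(x$results),
         n_bands = nrow(x$bands), ir_level = x$ir_level,
         ci_method = x$ci_method, conf_level = x$conf_level,
         reference_threshold = x$reference_threshold)
}

#' Threshold-impact rows of a study
#'
#' @param study A `lace_study` object.
#' @return Tibble of all threshold comparisons, one row per comparison,
#'   with `stratum` and `outcome` identifiers.
#' @export
threshold_impacts <- function(study) {
  stopifnot(inherits(study, "lace_study"))
  study$results |>
    dplyr::select("stratum", "outcome", "impact") |>
    dplyr::filter(!vapply(.data$impact, is.null, logical(1))) |>
    tidyr::unnest("impact")
}

#' Publication-style rounded study table
#'
#' Formats [tidy()] output at the conventional reporting precision: AUC and
#' its confidence bounds as percentages to one decimal, p-values shown as
#' `"<0.001"` below that level, likelihood ratios to two decimals, and the
#' equal-error threshold and intermediate-range bounds to one decimal.
#'
#' @param study A `lace_study` object.
#' @return A tibble of formatted character/numeric report columns.
#' @export
report_study <- function(study) {
  stopifnot(inherits(study, "lace_study"))
  tidy(study) |>
    dplyr::transmute(
      stratum = .data$stratum, outcome = .data$outcome, n = .data$n,
      n_events = .data$n_events,
      auc_pct = round(100 * .data$auc, 1),
      auc_ci = sprintf("%.1f-%.1f", 100 * .data$auc_ci_lower,
                       100 * .data$auc_ci_upper),
      p = dplyr::if_else(.data$p_value < 0.001, "<0.001",
                         sprintf("%.3f", .data$p_value)),
      lr_pos = round(.data$lr_pos, 2), lr_neg = round(.data$lr_neg, 2),
      theta0 = round(.data$theta0, 1),
      ir = sprintf("%.1f-%.1f", .data$ir_lower, .data$ir_upper)
    )
}
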