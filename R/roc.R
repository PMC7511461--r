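#' ROC curve with AUC and confidence interval
#'
#' Builds the threshold-wise ROC description of a score as a predictor of a
#' binary outcome under the positivity rule "score >= t means test
#' positive". For every candidate threshold `t`, sensitivity is the fraction
#' of events with score at or above `t` and specificity the fraction of
#' non-events below `t`; for whole-number scores the candidate grid is every
#' integer from the minimum score to one above the maximum, so
#' sensitivity starts at 1 and ends at 0 while specificity runs from 0 to 1.
#'
#' The AUC is the concordance (Mann-Whitney) statistic — the probability
#' that a random event outranks a random non-event, ties counted one half —
#' computed from ranks, not from the threshold grid. Its standard error uses
#' the Hanley-McNeil nonparametric formula by default; the DeLong
#' covariance estimator is available via `ci_method = "delong"`. The
#' reported p-value tests the AUC against 0.5 (two-sided z-test).
#'
#' @param x Numeric score vector, or a data frame (see
#'   `roc_curve.data.frame`).
#' @param outcomes Logical (or 0/1) event indicator, same length as the
#'   scores. Both at least one event and one non-event are required.
#' @param ci_method `"hanley-mcneil"` (default) or `"delong"`.
#' @param conf_level Confidence level for the AUC interval.
#' @param ... Passed between methods.
#' @return An object of class `lace_roc`: the per-threshold curve plus
#'   `auc`, `auc_se`, `auc_ci`, `p_value`, `n_pos`, `n_neg`. Use [tidy()]
#'   for the curve tibble, [glance()] for the one-row summary and
#'   `autoplot()` to draw the curve.
#' @examples
#' roc_curve(c(5, 6, 1, 2, 4), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#'
#' cohort <- simulate_cohort(cohort_config(n_per_band = rep(300, 5), seed = 1))
#' cohort |> add_lace() |> roc_curve(lace, died_within_6mo)
#' @export
roc_curve <- function(x, ...) UseMethod("roc_curve")

#' @rdname roc_curve
#' @export
roc_curve.default <- function(x, outcomes,
                              ci_method = c("hanley-mcneil", "delong"),
                              conf_level = 0.95, ...) {
  ci_method <- match.arg(ci_method)
  scores <- x
  if (!is.numeric(scores) || anyNA(scores)) {
    stop_bad_arg("scores", "must be numeric without missing values.")
  }
  if (is.numeric(outcomes) && all(outcomes %in% c(0, 1))) {
    outcomes <- outcomes == 1
  }
  check_flag(outcomes, "outcomes")
  if (length(scores) != length(outcomes)) {
    stop_bad_arg("outcomes", "must have the same length as the scores.")
  }
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined: need at least one event and one non-event.",
          class = "laceroc_undefined_auc")
  }

  pos <- scores[outcomes]; neg <- scores[!outcomes]
  thresholds <- if (is_whole(scores)) {
    seq(floor(min(scores)), floor(max(scores)) + 1)
  } else {
    u <- sort(unique(scores))
    step <- if (length(u) > 1) u[length(u)] - u[length(u) - 1] else 1
    c(u, max(u) + step)
  }
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))

  auc <- auc_concordance(scores, outcomes)
  se <- switch(ci_method,
               "hanley-mcneil" = hanley_mcneil_se(auc, n_pos, n_neg),
               "delong" = delong_se(pos, neg))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se)
       else as.numeric(auc == 0.5)

  structure(
    list(curve = tibble(threshold = thresholds, sensitivity = sens,
                        specificity = spec),
         auc = auc, auc_se = se, auc_ci = ci, conf_level = conf_level,
         p_value = p, n_pos = n_pos, n_neg = n_neg, ci_method = ci_method),
    class = "lace_roc"
  )
}

#' @rdname roc_curve
#' @param score,outcome For the data-frame method: unquoted column names of
#'   the score and the event indicator.
#' @export
roc_curve.data.frame <- function(x, score, outcome, ...) {
  s <- eval_tidy(enquo(score), x)
  o <- eval_tidy(enquo(outcome), x)
  roc_curve(s, o, ...)
}

# Mann-Whitney concordance from midranks; ties count one half
auc_concordance <- function(scores, outcomes) {
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(max(v, 0))
}

# DeLong: variance from the pseudo-value (placement) decomposition
delong_se <- function(pos, neg) {
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  v <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  sqrt(max(v, 0))
}

#' @export
print.lace_roc <- function(x, ...) {
  cat(sprintf("<lace_roc> AUC = %.3f (%d%% CI %.3f-%.3f, %s), %d events / %d non-events\n",
              x$auc, round(100 * x$conf_level), x$auc_ci[1], x$auc_ci[2],
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_curve
#' @method tidy lace_roc
#' @export
tidy.lace_roc <- function(x, ...) x$curve

#' @rdname roc_curve
#' @method glance lace_roc
#' @export
glance.lace_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_se = x$auc_se,
         auc_ci_lower = x$auc_ci[1], auc_ci_upper = x$auc_ci[2],
         conf_level = x$conf_level, p_value = x$p_value,
         n_pos = x$n_pos, n_neg = x$n_neg, ci_method = x$ci_method)
}

# piecewise-linear sensitivity/specificity between candidate thresholds
interp_curve <- function(curve, t) {
  rng <- range(curve$threshold)
  if (any(t < rng[1] | t > rng[2])) {
    stop_bad_arg("threshold", sprintf("must lie within the score range [%s, %s].",
                                      rng[1], rng[2]))
  }
  list(
    sensitivity = approx(curve$threshold, curve$sensitivity, xout = t,
                         ties = "ordered")$y,
    specificity = approx(curve$threshold, curve$specificity, xout = t,
                         ties = "ordered")$y
  )
}

#' Positive and negative likelihood ratios
#'
#' Computes LR+ = sensitivity / (1 - specificity) and LR- =
#' (1 - sensitivity) / specificity at a decision threshold. Non-integer
#' thresholds are evaluated by the same piecewise-linear interpolation of
#' the sensitivity and specificity curves used by [two_graph()]. A
#' specificity of exactly 1 with positive sensitivity yields an infinite
#' LR+ (reported, not an error), and symmetrically for LR-.
#'
#' @param curve A `lace_roc` object from [roc_curve()].
#' @param threshold Decision threshold(s), inside the curve's score range.
#' @return A tibble with columns `threshold`, `sensitivity`, `specificity`,
#'   `lr_pos`, `lr_neg`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_band = rep(300, 5), seed = 1))
#' rc <- cohort |> add_lace() |> roc_curve(lace, died_within_6mo)
#' likelihood_ratios(rc, 10)
#' @export
likelihood_ratios <- function(curve, threshold) {
  stopifnot(inherits(curve, "lace_roc"))
  check_number(threshold, "threshold")
  at <- interp_curve(curve$curve, threshold)
  dplyr::bind_cols(tibble(threshold = threshold),
                   lr_from_rates(at$sensitivity, at$specificity))
}

#' @rdname likelihood_ratios
#' @param sensitivity,specificity Rates in `[0, 1]` from which to compute
#'   the ratios directly.
#' @export
lr_from_rates <- function(sensitivity, specificity) {
  check_number(sensitivity, "sensitivity", lower = 0, upper = 1)
  check_number(specificity, "specificity", lower = 0, upper = 1)
  lr_pos <- ifelse(specificity < 1, sensitivity / (1 - specificity),
                   ifelse(sensitivity > 0, Inf, NaN))
  lr_neg <- ifelse(specificity > 0, (1 - sensitivity) / specificity,
                   ifelse(sensitivity < 1, Inf, NaN))
  tibble(sensitivity = sensitivity, specificity = specificity,
         lr_pos = lr_pos, lr_neg = lr_neg)
}
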