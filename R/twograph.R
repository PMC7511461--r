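#' Two-graph ROC threshold derivation
#'
#' Plots (conceptually) sensitivity and specificity as functions of the
#' decision threshold on one axis and derives the equal-error threshold and
#' the intermediate range. Between candidate thresholds both curves are
#' treated as piecewise-linear. The equal-error threshold `theta0` is the
#' crossing point where interpolated sensitivity equals specificity — the
#' threshold of maximum balanced accuracy. The intermediate range at
#' accuracy `level` (default 95%) runs from the threshold where sensitivity
#' falls to `level` (lower limit) up to the threshold where specificity
#' rises to `level` (upper limit); scores inside it are "borderline"
#' results. Lowering `level` (e.g. to 0.90) narrows the range.
#'
#' If a curve stays on the target level over a flat segment, the segment
#' midpoint is returned. A limit that is not attainable inside the score
#' range is clipped to the range end and flagged in `clipped`.
#'
#' @param curve A `lace_roc` object from [roc_curve()], or a data frame
#'   with columns `threshold`, `sensitivity`, `specificity`.
#' @param level Accuracy level for the intermediate range, in (0.5, 1).
#' @param ... Passed between methods.
#' @return An object of class `two_graph`: `theta0`, `equal_value`
#'   (the common sensitivity = specificity at `theta0`), `ir_lower`,
#'   `ir_upper`, `level`, and `clipped` (named logicals for the two
#'   limits). [tidy()] returns these as a one-row tibble; `autoplot()`
#'   draws the two-graph plot.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_band = rep(400, 5), seed = 2))
#' rc <- cohort |> add_lace() |> roc_curve(lace, died_within_6mo)
#' two_graph(rc)
#' two_graph(rc, level = 0.90)
#' @export
two_graph <- function(curve, level = 0.95, ...) UseMethod("two_graph")

#' @export
two_graph.lace_roc <- function(curve, level = 0.95, ...) {
  two_graph(curve$curve, level = level, ...)
}

#' @export
two_graph.data.frame <- function(curve, level = 0.95, ...) {
  needed <- c("threshold", "sensitivity", "specificity")
  if (!all(needed %in% names(curve))) {
    stop_bad_arg("curve", paste("needs columns",
                                paste(needed, collapse = ", ")))
  }
  if (!(is.numeric(level) && length(level) == 1 && level > 0.5 && level < 1)) {
    stop_bad_arg("level", "must be a single value in (0.5, 1).")
  }
  curve <- dplyr::arrange(curve, .data$threshold)
  t <- curve$threshold
  d <- curve$sensitivity - curve$specificity

  theta0 <- pwl_root(t, d)
  if (is.na(theta0)) {
    abort("Two-graph analysis failed: sensitivity and specificity curves do not cross within the score range.",
          class = "laceroc_no_crossing")
  }
  lo <- pwl_level(t, curve$sensitivity, level)     # sens is non-increasing
  hi <- pwl_level(t, curve$specificity, level)     # spec is non-decreasing

  structure(
    list(theta0 = theta0,
         equal_value = approx(t, curve$sensitivity, xout = theta0,
                              ties = "ordered")$y,
         ir_lower = lo$t, ir_upper = hi$t, level = level,
         clipped = c(lower = lo$clipped, upper = hi$clipped),
         curve = tibble::as_tibble(curve)),
    class = "two_graph"
  )
}

# root of a monotone non-increasing piecewise-linear function; midpoint of a
# flat zero segment; NA when no sign change occurs in range
pwl_root <- function(t, d) {
  hits <- which(d == 0)
  if (length(hits)) {
    runs <- split(hits, cumsum(c(1, diff(hits) != 1)))
    seg <- runs[[1]]
    return(mean(t[range(seg)]))
  }
  below <- which(d < 0)
  if (!length(below) || below[1] == 1) return(NA_real_)
  i <- below[1]
  t[i - 1] + d[i - 1] / (d[i - 1] - d[i]) * (t[i] - t[i - 1])
}

# threshold at which a monotone piecewise-linear curve passes `level`;
# flat segments at the level return their midpoint, unattainable levels
# clip to the nearer range end
pwl_level <- function(t, y, level) {
  hits <- which(y == level)
  if (length(hits)) {
    return(list(t = mean(t[range(hits)]), clipped = FALSE))
  }
  cross <- which(diff(sign(y - level)) != 0)
  if (!length(cross)) {
    increasing <- y[length(y)] >= y[1]
    above_all <- all(y > level)
    clip_low <- (increasing && above_all) || (!increasing && !above_all)
    return(list(t = if (clip_low) t[1] else t[length(t)], clipped = TRUE))
  }
  i <- cross[1]
  list(t = t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i]),
       clipped = FALSE)
}

#' @export
print.two_graph <- function(x, ...) {
  cat(sprintf("<two_graph> theta0 = %.2f (sens = spec = %.3f); IR_%d%% = %.2f-%.2f%s\n",
              x$theta0, x$equal_value, round(100 * x$level),
              x$ir_lower, x$ir_upper,
              if (any(x$clipped)) " [clipped]" else ""))
  invisible(x)
}

#' @rdname two_graph
#' @param x A `two_graph` object.
#' @method tidy two_graph
#' @export
tidy.two_graph <- function(x, ...) {
  tibble(theta0 = x$theta0, equal_value = x$equal_value,
         ir_lower = x$ir_lower, ir_upper = x$ir_upper, level = x$level,
         clipped_lower = unname(x$clipped["lower"]),
         clipped_upper = unname(x$clipped["upper"]))
}
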