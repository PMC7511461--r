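# internal validation helpers

stop_bad_arg <- function(field, msg) {
  abort(sprintf("Invalid `%s`: %s", field, msg), class = "laceroc_validation_error")
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         integerish = FALSE, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_bad_arg(field, "must be numeric and non-missing.")
  }
  if (!is.null(len) && length(x) != len) {
    stop_bad_arg(field, sprintf("must have length %d, not %d.", len, length(x)))
  }
  if (any(x < lower) || any(x > upper)) {
    stop_bad_arg(field, sprintf("must lie in [%s, %s].", lower, upper))
  }
  if (integerish && any(x != floor(x))) {
    stop_bad_arg(field, "must be a whole number.")
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || anyNA(x)) {
    stop_bad_arg(field, "must be TRUE/FALSE without missing values.")
  }
  invisible(x)
}

is_whole <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}
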