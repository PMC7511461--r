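#' Charlson condition mapping table (ICD-10, Quan 2005)
#'
#' Returns the bundled coding table that maps ICD-10 code prefixes to the 17
#' Charlson comorbidity condition groups, using the Quan et al. (2005)
#' ICD-10 coding algorithm with the original Charlson weights (1, 2, 3, 6).
#' Matching is by normalized prefix: codes are uppercased and dots stripped
#' before comparison against 3- and 4-character stems.
#'
#' The table is user-replaceable: supply `path` to load an alternative
#' dialect with the same three columns.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `condition`, `icd10_prefix`, `weight`.
#' @return A tibble with columns `condition` (character), `icd10_prefix`
#'   (character, dotless uppercase stem) and `weight` (integer).
#' @examples
#' charlson_map()
#' @export
charlson_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "charlson_icd10_quan2005.csv",
                                package = "laceroc", mustWork = TRUE)
  map <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("condition", "icd10_prefix", "weight")
  if (!all(needed %in% names(map))) {
    stop_bad_arg("path", paste("mapping file must have columns",
                               paste(needed, collapse = ", ")))
  }
  map$icd10_prefix <- normalize_icd10(map$icd10_prefix)
  tibble::as_tibble(map)
}

# severity hierarchies: when both members are flagged only the severe one
# contributes to the index
charlson_hierarchy <- function() {
  list(c(mild = "diabetes", severe = "diabetes_complicated"),
       c(mild = "mild_liver", severe = "severe_liver"),
       c(mild = "cancer", severe = "metastatic"))
}

normalize_icd10 <- function(codes) {
  gsub("[. ]", "", toupper(codes))
}

#' Charlson comorbidity flags and index from ICD-10 codes
#'
#' Flags each of the 17 Charlson condition groups that has at least one
#' matching ICD-10 code and computes the weighted comorbidity index.
#' A code matches a condition when its normalized form (uppercase, dot
#' stripped) starts with one of the condition's stems. Severity hierarchies
#' are applied: of diabetes with/without chronic complication, mild versus
#' moderate/severe liver disease, and any malignancy versus metastatic solid
#' tumour, only the more severe member counts. Unrecognized codes do not
#' match anything and are ignored.
#'
#' @param codes Character vector of ICD-10 codes for one episode; may be
#'   empty. An empty-string or non-character code is an error.
#' @param map Coding table, see [charlson_map()].
#' @return An object of class `charlson_result`: a list with `flags` (named
#'   logical over the condition groups, after hierarchy resolution) and
#'   `index` (non-negative integer).
#' @examples
#' charlson_flags(c("I21.4", "B20"))
#' charlson_flags(character())
#' @seealso [charlson_lace_subscore()], [add_charlson()]
#' @export
charlson_flags <- function(codes, map = charlson_map()) {
  if (length(codes) == 0) codes <- character()
  if (!is.character(codes)) {
    stop_bad_arg("codes", "must be a character vector of ICD-10 codes.")
  }
  if (anyNA(codes) || any(!nzchar(codes))) {
    stop_bad_arg("codes", "contains an empty or missing code.")
  }
  norm <- normalize_icd10(codes)
  conditions <- unique(map$condition)
  weights <- map$weight[match(conditions, map$condition)]
  names(weights) <- conditions

  flags <- vapply(conditions, function(cond) {
    stems <- map$icd10_prefix[map$condition == cond]
    any(vapply(norm, function(code) any(startsWith(code, stems)), logical(1)))
  }, logical(1))

  for (h in charlson_hierarchy()) {
    if (isTRUE(flags[[h[["severe"]]]])) flags[[h[["mild"]]]] <- FALSE
  }
  structure(
    list(flags = flags, index = as.integer(sum(weights[flags]))),
    class = "charlson_result"
  )
}

#' @export
print.charlson_result <- function(x, ...) {
  cat("<charlson_result> index =", x$index, "\n")
  on <- names(x$flags)[x$flags]
  cat(if (length(on)) paste(" conditions:", paste(on, collapse = ", "))
      else " no conditions flagged", "\n")
  invisible(x)
}

#' Charlson index for each episode in a table
#'
#' Data-frame verb: computes the Charlson comorbidity index for every row of
#' an episode table and appends it as `charlson_index`. The diagnosis-code
#' column may be a list-column of character vectors or a single character
#' column with codes separated by `sep` (the on-disk CSV convention).
#'
#' @param data Episode data frame.
#' @param codes Column holding the ICD-10 codes (unquoted); defaults to
#'   `icd10_codes`.
#' @param map Coding table, see [charlson_map()].
#' @param sep Separator used when `codes` is a character column.
#' @return `data` with an integer `charlson_index` column appended.
#' @examples
#' tibble::tibble(icd10_codes = c("I21;B20", "", "K25")) |> add_charlson()
#' @export
add_charlson <- function(data, codes = NULL, map = charlson_map(), sep = ";") {
  codes_q <- enquo(codes)
  col <- if (rlang::quo_is_null(codes_q)) data[["icd10_codes"]]
         else eval_tidy(codes_q, data)
  if (is.null(col)) stop_bad_arg("codes", "column not found in `data`.")
  sets <- if (is.list(col)) col else strsplit(ifelse(is.na(col), "", col), sep,
                                              fixed = TRUE)
  sets <- lapply(sets, function(x) x[nzchar(x)])
  data$charlson_index <- vapply(sets, function(x) charlson_flags(x, map)$index,
                                integer(1))
  data
}

#' LACE comorbidity subscore (C component) from a Charlson index
#'
#' Bins the Charlson comorbidity index into the LACE C component using the
#' published binning: index 0, 1, 2, 3 score their own value and any index of
#' 4 or more scores 5, so the component range is \{0, 1, 2, 3, 5\}.
#'
#' @param x A `charlson_result`, or a vector of non-negative Charlson
#'   index values.
#' @return Integer vector of C subscores in \{0, 1, 2, 3, 5\}.
#' @examples
#' charlson_lace_subscore(c(0, 1, 4, 12))
#' @export
charlson_lace_subscore <- function(x) {
  if (inherits(x, "charlson_result")) x <- x$index
  check_number(x, "index", lower = 0, integerish = TRUE)
  as.integer(ifelse(x >= 4, 5L, x))
}

#' Construct an ICD-10 code set realizing a target Charlson index
#'
#' Picks a hierarchy-consistent combination of Charlson condition groups
#' whose weights sum exactly to `index`, and returns one representative
#' ICD-10 code per chosen group. Used by the synthetic cohort generator to
#' emit diagnosis codes that round-trip through [charlson_flags()] to the
#' intended index, exercising the ICD-10 coding path end to end.
#'
#' @param index Target Charlson index, a whole number in `[0, 25]`.
#' @param map Coding table, see [charlson_map()].
#' @return Character vector of ICD-10 codes (empty for `index = 0`).
#' @examples
#' codes <- charlson_codes_for(7)
#' charlson_flags(codes)$index
#' @export
charlson_codes_for <- function(index, map = charlson_map()) {
  check_number(index, "index", lower = 0, upper = 25, integerish = TRUE, len = 1)
  # hierarchy-safe pools per weight: never mixes both members of a severity
  # pair, so the emitted set scores exactly the sum of the chosen weights
  pools <- list(
    `6` = "hiv",
    `3` = "severe_liver",
    `2` = c("renal", "paralysis", "diabetes_complicated", "cancer"),
    `1` = c("mi", "chf", "pvd", "cvd", "dementia", "copd", "rheumatic", "pud")
  )
  remaining <- as.integer(index)
  chosen <- character()
  for (w in c(6L, 3L, 2L, 1L)) {
    pool <- pools[[as.character(w)]]
    k <- min(length(pool), remaining %/% w)
    # greedy over {6,3,2,1} is exact here: the weight-1 pool (8 conditions)
    # always covers the remainder
    chosen <- c(chosen, pool[seq_len(k)])
    remaining <- remaining - k * w
  }
  stopifnot(remaining == 0L)
  vapply(chosen, function(cond) map$icd10_prefix[map$condition == cond][1],
         character(1), USE.NAMES = FALSE)
}
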