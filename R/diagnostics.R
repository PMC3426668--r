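#' Round half away from zero
#'
#' Commercial-rounding helper (`round()` in R rounds half to even): printed
#' percentages use half-up rounding.
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' 2x2 contingency table of a diagnostic test against truth
#'
#' @param cohort A cohort tibble with a `truth` column
#'   (`"case"`/`"control"`) and test columns coded
#'   `"positive"`/`"negative"` (logical columns are also accepted).
#' @param test Name of the test column.
#' @return A `cgm_ct` list with integer counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(cohort, test) {
  if (!test %in% names(cohort)) {
    stop("Unknown test column '", test, "'.", call. = FALSE)
  }
  if (!"truth" %in% names(cohort)) stop("Missing `truth` column.", call. = FALSE)
  pos <- as_positive(cohort[[test]])
  case <- cohort$truth == "case"
  contingency(tp = sum(case & pos), fp = sum(!case & pos),
              fn = sum(case & !pos), tn = sum(!case & !pos))
}

as_positive <- function(x) {
  if (is.logical(x)) return(x)
  x == "positive"
}

#' Construct a contingency table from counts
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A `cgm_ct` list.
#' @export
contingency <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("Counts must be non-negative with a positive total.", call. = FALSE)
  }
  structure(as.list(as.integer(counts)) |> rlang::set_names(names(counts)),
            class = "cgm_ct")
}

#' Diagnostic accuracy metrics with exact fractions
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values, and accuracy, each reported as the exact
#' fraction and as the integer percent under half-up rounding (the
#' convention of the published tables). A zero denominator yields an
#' undefined metric (`defined = FALSE`, NA values), not an error.
#'
#' @param ct A [contingency()] table.
#' @return Tibble `metric, numerator, denominator, fraction, percent,
#'   defined`.
#' @export
metrics <- function(ct) {
  stopifnot(inherits(ct, "cgm_ct"))
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  spec <- tibble::tribble(
    ~metric,       ~numerator,    ~denominator,
    "sensitivity", ct$tp,         ct$tp + ct$fn,
    "specificity", ct$tn,         ct$tn + ct$fp,
    "ppv",         ct$tp,         ct$tp + ct$fp,
    "npv",         ct$tn,         ct$tn + ct$fn,
    "accuracy",    ct$tp + ct$tn, n
  )
  spec |>
    dplyr::mutate(
      defined = .data$denominator > 0,
      fraction = ifelse(.data$defined,
                        .data$numerator / .data$denominator, NA_real_),
      percent = ifelse(.data$defined,
                       round_half_up(100 * .data$fraction), NA_real_)
    ) |>
    dplyr::select("metric", "numerator", "denominator", "fraction",
                  "percent", "defined")
}

#' Discordant-pair summary of two paired tests
#'
#' @param cohort Cohort tibble.
#' @param test1,test2 Test column names.
#' @param subset Optional logical vector restricting the rows (e.g. cases
#'   only, to compare sensitivities).
#' @return A `cgm_paired` list with concordant counts `both_pos`,
#'   `both_neg` and discordant counts `b` (test1+/test2-) and `c`
#'   (test1-/test2+).
#' @export
paired_outcomes <- function(cohort, test1, test2, subset = NULL) {
  x <- as_positive(cohort[[test1]])
  y <- as_positive(cohort[[test2]])
  if (!is.null(subset)) { x <- x[subset]; y <- y[subset] }
  structure(list(both_pos = sum(x & y), b = sum(x & !y),
                 c = sum(!x & y), both_neg = sum(!x & !y)),
            class = "cgm_paired")
}

#' McNemar test for paired diagnostic proportions
#'
#' Compares two tests on the same patients through their discordant counts
#' `b` and `c`. The exact variant is the two-sided binomial test of
#' `b` successes in `b + c` trials at probability 1/2 (doubled smaller
#' tail, capped at 1); the corrected variant is the continuity-corrected
#' chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df (numerator clamped at 0).
#' With `method = "auto"` the exact test is used when `b + c < 25`.
#'
#' @param x A [paired_outcomes()] object, or a numeric `c(b, c)` pair.
#' @param method `"auto"`, `"exact"` or `"corrected"`.
#' @return A `cgm_mcnemar` list: `b`, `c`, `method`, `statistic` (corrected
#'   only), `p_value`, `degenerate` (TRUE when `b + c = 0`, where p = 1).
#' @export
mcnemar_test <- function(x, method = c("auto", "exact", "corrected")) {
  method <- match.arg(method)
  if (inherits(x, "cgm_paired")) { b <- x$b; cc <- x$c } else {
    stopifnot(is.numeric(x), length(x) == 2L)
    b <- x[1]; cc <- x[2]
  }
  n <- b + cc
  if (n == 0) {
    return(structure(list(b = b, c = cc, method = method, statistic = NA_real_,
                          p_value = 1, degenerate = TRUE),
                     class = "cgm_mcnemar"))
  }
  if (method == "auto") method <- if (n < 25) "exact" else "corrected"
  if (method == "exact") {
    k <- min(b, cc)
    p <- min(1, 2 * stats::pbinom(k, n, 0.5))
    stat <- NA_real_
  } else {
    stat <- max(0, abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(b = b, c = cc, method = method, statistic = stat,
                 p_value = p, degenerate = FALSE),
            class = "cgm_mcnemar")
}

#' @export
print.cgm_mcnemar <- function(x, ...) {
  cat(sprintf("McNemar (%s): b = %d, c = %d, p = %.4g\n",
              x$method, x$b, x$c, x$p_value))
  invisible(x)
}

#' Chi-square or Fisher test for an unpaired 2x2 comparison
#'
#' Pearson's chi-square (without continuity correction) when every expected
#' cell exceeds `min_expected`, Fisher's exact test (two-sided, by
#' hypergeometric probability ordering) when any expected cell is at or
#' below it — the small-sample rule of the analysis plan.
#'
#' @param counts 2x2 matrix or length-4 vector (row-wise `a, b, c, d`).
#' @param min_expected Expected-count threshold (default 5; cells at or
#'   below it trigger Fisher).
#' @return List `method` (`"chisq"`/`"fisher"`), `p_value`, `statistic`
#'   (chi-square only).
#' @export
categorical_test <- function(counts, min_expected = 5) {
  m <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  if (sum(m) == 0) stop("Empty table.", call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= min_expected)) {
    list(method = "fisher", p_value = stats::fisher.test(m)$p.value,
         statistic = NA_real_)
  } else {
    ht <- stats::chisq.test(m, correct = FALSE)
    list(method = "chisq", p_value = ht$p.value,
         statistic = unname(ht$statistic))
  }
}

#' OR-combination of diagnostic tests
#'
#' Adds a derived column that is positive when any of the component tests
#' is positive — the "CGM and/or troponin" composite.
#'
#' @param cohort Cohort tibble.
#' @param tests Character vector of test column names (non-empty).
#' @param name Name of the derived column (default the tests joined by
#'   `"_or_"`).
#' @return The cohort with the derived column appended.
#' @export
combine_tests_or <- function(cohort, tests, name = NULL) {
  if (length(tests) == 0L) stop("Empty test list.", call. = FALSE)
  missing <- setdiff(tests, names(cohort))
  if (length(missing)) {
    stop("Unknown tests: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(name)) name <- paste(tests, collapse = "_or_")
  any_pos <- Reduce(`|`, lapply(tests, function(t) as_positive(cohort[[t]])))
  cohort[[name]] <- ifelse(any_pos, "positive", "negative")
  cohort
}

#' Screening yield of adding a test to a negative gatekeeper workup
#'
#' Restricts the cohort to patients negative on all gatekeeper tests and
#' counts how many additional true cases the candidate test flags
#' (`additional_tp`) and how many false positives it generates (`fp`).
#' NNT = subgroup size / additional true positives; NNH = subgroup size /
#' false positives; both half-up rounded to one decimal, and flagged
#' undefined (NA) when their numerator count is zero.
#'
#' @param cohort Cohort tibble with `truth`.
#' @param test Candidate test column.
#' @param gatekeepers Character vector of gatekeeper test columns.
#' @return List `n_subgroup`, `additional_tp`, `fp`, `nnt`, `nnh`,
#'   `nnt_defined`, `nnh_defined`.
#' @export
screening_yield <- function(cohort, test, gatekeepers) {
  stopifnot(length(gatekeepers) >= 1L)
  neg_all <- Reduce(`&`, lapply(gatekeepers,
                                function(t) !as_positive(cohort[[t]])))
  sub <- cohort[neg_all, , drop = FALSE]
  if (nrow(sub) == 0L) stop("Empty gatekeeper-negative subgroup.", call. = FALSE)
  pos <- as_positive(sub[[test]])
  case <- sub$truth == "case"
  add_tp <- sum(case & pos)
  fp <- sum(!case & pos)
  n <- nrow(sub)
  list(
    n_subgroup = n,
    additional_tp = add_tp,
    fp = fp,
    nnt = if (add_tp > 0) round_half_up(n / add_tp, 1) else NA_real_,
    nnh = if (fp > 0) round_half_up(n / fp, 1) else NA_real_,
    nnt_defined = add_tp > 0,
    nnh_defined = fp > 0
  )
}

#' Table-shaped diagnostic evaluation of a cohort
#'
#' Computes the full metric table for each named test: a long tibble in the
#' published layout (`metric, test, percent, numerator, denominator`).
#'
#' @param cohort Cohort tibble with `truth`.
#' @param tests Character vector of test columns.
#' @return Tibble of metrics for all tests.
#' @export
evaluate_cohort <- function(cohort, tests) {
  purrr::map(tests, function(t) {
    metrics(confusion(cohort, t)) |>
      dplyr::mutate(test = t, .after = "metric")
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("metric", "test", "percent", "numerator", "denominator")
}
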