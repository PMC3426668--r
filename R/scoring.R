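#' Build a stratified reference-range set
#'
#' @param ranges Tibble with columns `stratum`, `name`, `low`, `high`
#'   (closed intervals, `low <= high`).
#' @return A `cgm_ranges` tibble.
#' @export
reference_ranges <- function(ranges) {
  ranges <- tibble::as_tibble(ranges)
  stopifnot(all(c("stratum", "name", "low", "high") %in% names(ranges)))
  bad <- which(ranges$low > ranges$high)
  if (length(bad)) {
    stop("`low` exceeds `high` for: ",
         paste(ranges$name[bad], collapse = ", "), call. = FALSE)
  }
  structure(ranges, class = c("cgm_ranges", class(tibble::tibble())))
}

#' Score a parameter vector against its reference ranges
#'
#' The penalty score: every parameter of the active stratum's set must lie
#' inside its closed reference interval for a score of zero (a negative,
#' i.e. normal, finding); each out-of-range parameter subtracts one point,
#' and any score below zero is a positive (pathological) finding. The
#' score's magnitude carries no severity meaning — the result is
#' dichotomous by construction.
#'
#' Missing (NA) parameter values — e.g. from degenerate loops — count as
#' out of range by default (`na_out_of_range = FALSE` drops them instead);
#' they are listed separately in the result.
#'
#' @param pv A parameter tibble (`name`, `value`).
#' @param ranges A [reference_ranges()] tibble.
#' @param stratum Stratum key to score against (default `"sinus_female"`
#'   style keys are up to the caller; any label present in `ranges`).
#' @param na_out_of_range Whether NA values penalise (default TRUE).
#' @return A `cgm_result`: list with `score` (integer <= 0),
#'   `classification` (`"positive"`/`"negative"`), `out_of_range`
#'   (character), `missing_value` (character), `n_parameters`.
#' @export
score_parameters <- function(pv, ranges, stratum, na_out_of_range = TRUE) {
  rr <- dplyr::filter(tibble::as_tibble(ranges), .data$stratum == !!stratum)
  missing_ranges <- setdiff(pv$name, rr$name)
  if (length(missing_ranges)) {
    stop("No reference range in stratum '", stratum, "' for: ",
         paste(missing_ranges, collapse = ", "), call. = FALSE)
  }
  j <- dplyr::inner_join(tibble::as_tibble(pv)[, c("name", "value")],
                         rr[, c("name", "low", "high")], by = "name")
  is_na <- is.na(j$value)
  out <- !is_na & (j$value < j$low | j$value > j$high)
  penal_na <- if (na_out_of_range) is_na else rep(FALSE, nrow(j))
  score <- -(sum(out) + sum(penal_na))
  structure(
    list(score = as.integer(score),
         classification = if (score < 0) "positive" else "negative",
         out_of_range = j$name[out],
         missing_value = j$name[is_na],
         n_parameters = nrow(j),
         stratum = stratum),
    class = "cgm_result"
  )
}

#' @export
print.cgm_result <- function(x, ...) {
  cat(sprintf("<cgm_result> score %d -> %s CGM (%d parameters, stratum %s)\n",
              x$score, x$classification, x$n_parameters, x$stratum))
  if (length(x$out_of_range)) {
    cat("  out of range:", paste(x$out_of_range, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Calibrate reference ranges from a control population
#'
#' Per parameter and stratum, the range is the central `coverage` empirical
#' quantile interval (linear-interpolation quantiles): probabilities
#' `(1 - coverage)/2` and `1 - (1 - coverage)/2`. `coverage = 1` gives the
#' min-max envelope, under which every calibration control scores zero.
#'
#' @param controls Long tibble of control parameter vectors: columns
#'   `subject`, `stratum`, `name`, `value`.
#' @param coverage Central coverage `q`, `0 < q <= 1` (default 0.99).
#' @param min_controls Minimum control vectors per stratum (default 20).
#' @return A [reference_ranges()] tibble.
#' @export
calibrate_reference_ranges <- function(controls, coverage = 0.99,
                                       min_controls = 20) {
  stopifnot(coverage > 0, coverage <= 1)
  controls <- tibble::as_tibble(controls)
  stopifnot(all(c("subject", "stratum", "name", "value") %in% names(controls)))
  counts <- controls |>
    dplyr::distinct(.data$stratum, .data$subject) |>
    dplyr::count(.data$stratum)
  small <- counts$stratum[counts$n < min_controls]
  if (length(small)) {
    stop("Insufficient controls (< ", min_controls, ") in strata: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  a <- (1 - coverage) / 2
  controls |>
    dplyr::group_by(.data$stratum, .data$name) |>
    dplyr::summarise(
      low = stats::quantile(.data$value, a, type = 7, na.rm = TRUE,
                            names = FALSE),
      high = stats::quantile(.data$value, 1 - a, type = 7, na.rm = TRUE,
                             names = FALSE),
      .groups = "drop"
    ) |>
    reference_ranges()
}
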