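#' Tidy a CGM scoring result
#'
#' One row per scored parameter with its in/out-of-range status.
#' @param x A `cgm_result`.
#' @param ... Unused.
#' @return Tibble `name, status` with status in
#'   `in_range` / `out_of_range` / `missing`.
#' @export
tidy.cgm_result <- function(x, ...) {
  tibble::tibble(
    name = c(x$out_of_range, x$missing_value),
    status = rep(c("out_of_range", "missing"),
                 c(length(x$out_of_range), length(x$missing_value)))
  )
}

#' Glance at a CGM scoring result
#' @param x A `cgm_result`.
#' @param ... Unused.
#' @return One-row tibble with `score`, `classification`, `n_parameters`,
#'   `n_out_of_range`, `stratum`.
#' @export
glance.cgm_result <- function(x, ...) {
  tibble::tibble(score = x$score, classification = x$classification,
                 n_parameters = x$n_parameters,
                 n_out_of_range = length(x$out_of_range),
                 stratum = x$stratum)
}

#' Tidy a McNemar comparison
#' @param x A `cgm_mcnemar`.
#' @param ... Unused.
#' @return One-row tibble `b, c, method, statistic, p_value, degenerate`.
#' @export
tidy.cgm_mcnemar <- function(x, ...) {
  tibble::tibble(b = x$b, c = x$c, method = x$method,
                 statistic = x$statistic, p_value = x$p_value,
                 degenerate = x$degenerate)
}

#' Tidy a contingency table into metric rows
#' @param x A `cgm_ct`.
#' @param ... Unused.
#' @return The [metrics()] tibble.
#' @export
tidy.cgm_ct <- function(x, ...) metrics(x)

#' Glance at a contingency table
#' @param x A `cgm_ct`.
#' @param ... Unused.
#' @return One-row tibble of the four counts and `n`.
#' @export
glance.cgm_ct <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
                 n = x$tp + x$fp + x$fn + x$tn)
}
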