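#' Plot a heart-vector trajectory as plane projections
#'
#' Shows the loops in the three coordinate planes (X-Y: oblique sagittal;
#' Y-Z: frontal; X-Z: perpendicular sagittal).
#'
#' @param object A `vcg_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vcg_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(plane = "oblique sagittal (X-Y)", h = df$X, v = df$Y),
    tibble::tibble(plane = "frontal (Y-Z)", h = df$Y, v = df$Z),
    tibble::tibble(plane = "sagittal (X-Z)", h = df$X, v = df$Z)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$h, .data$v)) +
    ggplot2::geom_path(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mV", y = "mV",
                  title = "Heart-vector loops by projection plane") +
    ggplot2::theme_minimal()
}

#' Plot median loops with their maximum vectors
#'
#' @param object A `cgm_median_loops` object.
#' @param ... Unused.
#' @return A ggplot of the three median loops in the oblique-sagittal
#'   plane, maximum vectors drawn as segments from the origin.
#' @export
autoplot.cgm_median_loops <- function(object, ...) {
  loops <- purrr::imap(object[c("P", "R", "T")], function(m, nm) {
    dplyr::mutate(tibble::as_tibble(m), loop = nm)
  }) |> dplyr::bind_rows()
  mv <- object$max_vectors
  ggplot2::ggplot(loops, ggplot2::aes(.data$X, .data$Y, colour = .data$loop)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_segment(
      data = mv,
      ggplot2::aes(x = 0, y = 0, xend = .data$X, yend = .data$Y,
                   colour = .data$loop),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "X (mV)", y = "Y (mV)",
                  title = "Median loops and maximum vectors",
                  subtitle = "Oblique-sagittal plane") +
    ggplot2::theme_minimal()
}

#' Bar chart of diagnostic yield across tests
#'
#' The published figure's layout: correctly classified patients per test,
#' split by endpoint (sensitivity among cases, specificity among controls,
#' accuracy overall).
#'
#' @param cohort Cohort tibble with `truth`.
#' @param tests Character vector of test columns.
#' @return A ggplot.
#' @export
plot_diagnostic_yield <- function(cohort, tests) {
  tab <- evaluate_cohort(cohort, tests) |>
    dplyr::filter(.data$metric %in% c("sensitivity", "specificity",
                                      "accuracy"))
  ggplot2::ggplot(tab, ggplot2::aes(.data$test, .data$numerator,
                                    fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      ggplot2::aes(label = paste0(.data$percent, "%")),
      position = ggplot2::position_dodge(width = 0.9), vjust = -0.3,
      size = 3) +
    ggplot2::labs(x = NULL, y = "correctly classified patients",
                  title = "Diagnostic yield by test") +
    ggplot2::theme_minimal()
}
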