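#' Read a five-lead or electrode-potential signal file
#'
#' Accepts the two delimited-text dialects: `t,phi1,phi2,phi3,phi4`
#' (electrode potentials, mV, time in seconds) or `t,D,A,I,Ho,Ve` (leads).
#' Potentials are converted to leads on the way in.
#'
#' @param path CSV file path.
#' @return A `cgm_leads` tibble.
#' @export
read_signal_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("phi1", "phi2", "phi3", "phi4") %in% names(df))) {
    leads_from_potentials(df)
  } else if (all(c("D", "A", "I", "Ho", "Ve") %in% names(df))) {
    fs <- if ("t" %in% names(df) && nrow(df) >= 2) 1 / stats::median(diff(df$t)) else 1000
    if (!"t" %in% names(df)) df$t <- seq(0, by = 1 / fs, length.out = nrow(df))
    new_leads(df[, c("t", "D", "A", "I", "Ho", "Ve")], fs)
  } else {
    stop("Unrecognised signal header: expected phi1..phi4 or D,A,I,Ho,Ve.",
         call. = FALSE)
  }
}

#' Write / read a heart-vector trajectory as CSV (`t,X,Y,Z`)
#' @param traj A `vcg_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a `vcg_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj)[, c("t", "X", "Y", "Z")], path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  fs <- if (nrow(df) >= 2) 1 / stats::median(diff(df$t)) else 1000
  as_trajectory(df, sampling_rate = fs)
}

#' Write beat annotations as CSV (`beat,fiducial,sample_index`)
#' @param ann A `cgm_annotations` tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(ann, path) {
  long <- tidyr::pivot_longer(tibble::as_tibble(ann), -"beat",
                              names_to = "fiducial",
                              values_to = "sample_index")
  readr::write_csv(long, path)
  invisible(path)
}

#' Write / read a parameter vector as CSV (`name,class,units,value`)
#' @param pv A `cgm_parameters` tibble.
#' @param path CSV file path.
#' @return `path` invisibly, or the parameter tibble.
#' @export
write_parameters_csv <- function(pv, path) {
  readr::write_csv(tibble::as_tibble(pv), path)
  invisible(path)
}

#' @rdname write_parameters_csv
#' @export
read_parameters_csv <- function(path) {
  structure(readr::read_csv(path, show_col_types = FALSE),
            class = c("cgm_parameters", class(tibble::tibble())))
}

#' Write / read reference ranges as JSON (`{stratum: {name: [low, high]}}`)
#' @param ranges A [reference_ranges()] tibble.
#' @param path JSON file path.
#' @return `path` invisibly, or the ranges tibble.
#' @export
write_ranges_json <- function(ranges, path) {
  nested <- split(tibble::as_tibble(ranges), ranges$stratum)
  obj <- purrr::map(nested, function(df) {
    rlang::set_names(purrr::map2(df$low, df$high, c), df$name)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ranges_json
#' @export
read_ranges_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::imap(obj, function(params, stratum) {
    tibble::tibble(
      stratum = stratum,
      name = names(params),
      low = unname(purrr::map_dbl(params, 1)),
      high = unname(purrr::map_dbl(params, 2))
    )
  }) |>
    dplyr::bind_rows() |>
    reference_ranges()
}

#' Write / read a cohort table as CSV
#' @param cohort A `cgm_cohort` tibble.
#' @param path CSV file path.
#' @return `path` invisibly, or the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  structure(readr::read_csv(path, show_col_types = FALSE),
            class = c("cgm_cohort", class(tibble::tibble())))
}

#' Write a CGM result as JSON
#' @param result A `cgm_result`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  jsonlite::write_json(
    list(score = result$score, classification = result$classification,
         out_of_range = result$out_of_range,
         missing_value = result$missing_value,
         n_parameters = result$n_parameters, stratum = result$stratum),
    path, auto_unbox = TRUE, digits = NA, null = "list")
  invisible(path)
}
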