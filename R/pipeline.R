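#' Pipeline configuration
#'
#' Bundles every tunable of the signal chain plus I/O paths into a single
#' JSON-serialisable object.
#'
#' @param height_ratio Electrode height ratio (default 0.7).
#' @param detector A [cgm_config()].
#' @param ranges_file Optional path to a reference-range JSON.
#' @param stratum Stratum key for scoring (default `"sinus"`).
#' @param seed Integer seed for any stochastic stage.
#' @param out_dir Output directory for artifacts (default `tempdir()`).
#' @return A list of class `cgm_pipeline_config`.
#' @export
pipeline_config <- function(height_ratio = 0.7, detector = cgm_config(),
                            ranges_file = NULL, stratum = "sinus",
                            seed = 1L, out_dir = tempdir()) {
  structure(list(height_ratio = height_ratio, detector = detector,
                 ranges_file = ranges_file, stratum = stratum,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "cgm_pipeline_config")
}

#' Serialise / restore a pipeline configuration as JSON
#' @param cfg A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` invisibly, or the restored config.
#' @export
write_pipeline_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$detector <- unclass(obj$detector)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- do.call(cgm_config, as.list(obj$detector))
  pipeline_config(height_ratio = obj$height_ratio, detector = det,
                  ranges_file = obj$ranges_file, stratum = obj$stratum,
                  seed = obj$seed, out_dir = obj$out_dir)
}

pipeline_log <- function(stage, msg, quiet) {
  if (!quiet) message(sprintf("[%s] %s: %s",
                              format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full signal-to-score pipeline on one recording
#'
#' Executes geometry (lead projection), beat detection, loop segmentation,
#' median-loop computation, parameter extraction and — when reference
#' ranges are available — penalty scoring; writes the trajectory, parameter
#' and result files into `cfg$out_dir`. Stage errors are re-raised with the
#' failing stage named.
#'
#' @param signal A `cgm_leads` object, a `vcg_trajectory`, or the path of a
#'   signal CSV.
#' @param cfg A [pipeline_config()].
#' @param ranges Optional [reference_ranges()] tibble (overrides
#'   `cfg$ranges_file`).
#' @param quiet Suppress stage log messages (default TRUE).
#' @return List with `trajectory`, `annotations`, `median_loops`,
#'   `parameters`, `result` (NULL without ranges), `warnings`, and `files`
#'   (paths written).
#' @export
run_pipeline <- function(signal, cfg = pipeline_config(), ranges = NULL,
                         quiet = TRUE) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    pipeline_log(name, sprintf("done in %.2fs",
                               as.numeric(Sys.time() - t0, units = "secs")),
                 quiet)
    out
  }
  model <- electrode_model(cfg$height_ratio)
  traj <- stage("geometry", {
    if (is.character(signal)) signal <- read_signal_csv(signal)
    if (inherits(signal, "vcg_trajectory")) signal
    else project_to_xyz(signal, model)
  })
  ann <- stage("beats", detect_beats(traj, cfg$detector))
  for (w in attr(ann, "warnings")) pipeline_log("beats", w, quiet)
  loops <- stage("loops", segment_loops(traj, ann))
  ml <- stage("median", median_loops(loops,
                                     grid_points = cfg$detector$grid_points,
                                     min_beats = cfg$detector$min_beats))
  pv <- stage("parameters", extract_all(traj, ann, cfg$detector))
  if (is.null(ranges) && !is.null(cfg$ranges_file)) {
    ranges <- read_ranges_json(cfg$ranges_file)
  }
  result <- if (!is.null(ranges)) {
    stage("scoring", score_parameters(pv, ranges, cfg$stratum))
  } else NULL

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    trajectory = write_trajectory_csv(traj, file.path(cfg$out_dir, "trajectory.csv")),
    parameters = write_parameters_csv(pv, file.path(cfg$out_dir, "parameters.csv"))
  )
  if (!is.null(result)) {
    files <- c(files, result = write_result_json(
      result, file.path(cfg$out_dir, "result.json")))
  }
  list(trajectory = traj, annotations = ann, median_loops = ml,
       parameters = pv, result = result,
       warnings = attr(ann, "warnings"), files = files)
}

#' Simulate signal and cohort files from spec files
#'
#' Deterministic file-level front end of the generators: reads a
#' `vcg_config`/`cohort_spec` JSON, writes the generated artifacts next to
#' `out_dir` and a manifest listing them. Specs without an explicit seed
#' are rejected.
#'
#' @param spec Path of a JSON spec with a top-level `kind` field
#'   (`"vcg"` or `"cohort"`) plus the fields of [vcg_config()] or
#'   [cohort_spec()].
#' @param out_dir Output directory.
#' @return Paths of the written files (invisibly), including
#'   `manifest.json`.
#' @export
simulate_files <- function(spec, out_dir = tempdir()) {
  obj <- jsonlite::read_json(spec, simplifyVector = TRUE)
  if (is.null(obj$seed)) {
    stop("Simulation specs must carry an explicit `seed`.", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (identical(obj$kind, "vcg")) {
    args <- obj[setdiff(names(obj), "kind")]
    if (!is.null(args$loops)) args$loops <- tibble::as_tibble(args$loops)
    cfg <- do.call(vcg_config, args)
    sim <- synth_vcg(cfg)
    files["trajectory"] <- write_trajectory_csv(
      sim$trajectory, file.path(out_dir, "trajectory.csv"))
    files["truth"] <- file.path(out_dir, "truth.csv")
    readr::write_csv(sim$truth$beats, files["truth"])
  } else if (identical(obj$kind, "cohort")) {
    sp <- cohort_spec(obj$n_cases, obj$n_controls,
                      tibble::as_tibble(obj$tests),
                      rho = obj$rho %||% 0, seed = obj$seed)
    files["cohort"] <- write_cohort_csv(synth_cohort(sp),
                                        file.path(out_dir, "cohort.csv"))
  } else {
    stop("Spec `kind` must be 'vcg' or 'cohort'.", call. = FALSE)
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(as.list(files), manifest, auto_unbox = TRUE)
  invisible(c(files, manifest = manifest))
}
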