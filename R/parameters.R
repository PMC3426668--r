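#' @keywords internal
param_row <- function(name, class, units, value) {
  tibble::tibble(name = name, class = class, units = units,
                 value = as.numeric(value))
}

deg <- function(x) x * 180 / pi

#' Angle parameters of the median loops
#'
#' Longitude is the angle of a maximum vector within the oblique-sagittal
#' (X-Y) plane, `atan2(Y, X)`, in (-180, 180]; latitude is its elevation out
#' of that plane toward +Z, in \[-90, 90\]. The pairwise spatial angles
#' between the P, R and T maximum vectors (0-180 degrees) are included —
#' the R-T angle is the classic marker of repolarisation discordance.
#'
#' @param ml A [median_loops()] object.
#' @return Parameter tibble (`name, class, units, value`).
#' @export
angle_params <- function(ml) {
  mv <- ml$max_vectors
  if (any(mv$magnitude == 0)) {
    stop("Undefined angle: a maximum vector has zero magnitude.",
         call. = FALSE)
  }
  vecs <- rlang::set_names(
    purrr::map(mv$loop, ~as.numeric(mv[mv$loop == .x, c("X", "Y", "Z")])),
    mv$loop
  )
  per_loop <- purrr::imap(vecs, function(v, nm) {
    lo <- deg(atan2(v[2], v[1]))
    if (lo <= -180) lo <- lo + 360
    la <- deg(asin(pmin(1, pmax(-1, v[3] / vnorm(v)))))
    dplyr::bind_rows(
      param_row(paste0(nm, "_max_longitude"), "angle", "deg", lo),
      param_row(paste0(nm, "_max_latitude"), "angle", "deg", la)
    )
  })
  pair <- function(a, b) {
    u <- vecs[[a]] / vnorm(vecs[[a]]); v <- vecs[[b]] / vnorm(vecs[[b]])
    deg(acos(pmin(1, pmax(-1, sum(u * v)))))
  }
  dplyr::bind_rows(
    dplyr::bind_rows(per_loop),
    param_row("angle_PR", "angle", "deg", pair("P", "R")),
    param_row("angle_RT", "angle", "deg", pair("R", "T")),
    param_row("angle_PT", "angle", "deg", pair("P", "T"))
  )
}

#' Amplitude parameters of the median loops
#'
#' Per-axis minima and maxima of each median loop, the maximum-vector
#' magnitudes, the R/T and P/R magnitude ratios, and the ST level: the
#' heart-vector magnitude measured `st_ms` milliseconds after the J point
#' (the start of the T/ST loop).
#'
#' @param ml A [median_loops()] object.
#' @param st_ms ST measurement offset after J, default 20 ms.
#' @return Parameter tibble.
#' @export
amplitude_params <- function(ml, st_ms = 20) {
  per_loop <- purrr::imap(ml[c("P", "R", "T")], function(m, nm) {
    purrr::map(c("X", "Y", "Z"), function(ax) {
      dplyr::bind_rows(
        param_row(paste0(nm, "_", ax, "_min"), "amplitude", "mV", min(m[[ax]])),
        param_row(paste0(nm, "_", ax, "_max"), "amplitude", "mV", max(m[[ax]]))
      )
    }) |> dplyr::bind_rows()
  })
  mv <- ml$max_vectors
  mag <- rlang::set_names(mv$magnitude, mv$loop)
  tl <- ml$T
  st_level <- if (nrow(tl) >= 2L) {
    stats::approx(tl$t, sqrt(tl$X^2 + tl$Y^2 + tl$Z^2),
                  xout = min(st_ms / 1000, max(tl$t)), rule = 2)$y
  } else NA_real_
  dplyr::bind_rows(
    dplyr::bind_rows(per_loop),
    param_row("P_max_magnitude", "amplitude", "mV", mag[["P"]]),
    param_row("R_max_magnitude", "amplitude", "mV", mag[["R"]]),
    param_row("T_max_magnitude", "amplitude", "mV", mag[["T"]]),
    param_row("ratio_RT_magnitude", "amplitude", "1", mag[["R"]] / mag[["T"]]),
    param_row("ratio_PR_magnitude", "amplitude", "1", mag[["P"]] / mag[["R"]]),
    param_row("ST_level", "amplitude", "mV", st_level)
  )
}

principal_extents <- function(loop) {
  M <- cbind(loop$X, loop$Y, loop$Z)
  M <- sweep(M, 2, colMeans(M))
  sv <- svd(M, nu = 0, nv = 0)$d / sqrt(max(1, nrow(M) - 1))
  sort(sv, decreasing = TRUE)
}

#' Shape parameters of a loop
#'
#' Principal-extent decomposition of the centred loop points into extents
#' `e1 >= e2 >= e3`; eccentricity `sqrt(1 - (e2/e1)^2)` (0 for a circle, 1
#' for a straight line) and planarity `1 - e3/e1` (1 for a planar loop).
#'
#' @param loop Loop tibble with `X`, `Y`, `Z`.
#' @param prefix Name prefix (e.g. `"R"`).
#' @return Parameter tibble.
#' @export
shape_params <- function(loop, prefix = "R") {
  if (nrow(loop) < 2L) stop("Loop has fewer than 2 points.", call. = FALSE)
  e <- principal_extents(loop)
  if (e[1] <= 0) {
    ecc <- 1; pla <- 0  # all points coincide: degenerate
  } else {
    ecc <- sqrt(max(0, 1 - (e[2] / e[1])^2))
    pla <- 1 - e[3] / e[1]
  }
  dplyr::bind_rows(
    param_row(paste0(prefix, "_eccentricity"), "shape", "1", ecc),
    param_row(paste0(prefix, "_planarity"), "shape", "1", pla)
  )
}

#' Octant potential distribution of a loop
#'
#' Apportions the loop's time-weighted magnitude integral to the eight sign
#' octants of the XYZ system (fractions summing to 1). Zero coordinates are
#' assigned to the positive side. An all-zero loop returns uniform fractions
#' with a `degenerate` attribute.
#'
#' @param loop Loop tibble with `X`, `Y`, `Z` (uniformly sampled in time).
#' @param prefix Name prefix.
#' @return Parameter tibble of eight `fraction` entries named
#'   `<prefix>_octant_<sx><sy><sz>` with signs `p`/`m`.
#' @export
octant_params <- function(loop, prefix = "R") {
  if (nrow(loop) == 0L) stop("Empty loop.", call. = FALSE)
  w <- sqrt(loop$X^2 + loop$Y^2 + loop$Z^2)
  key <- paste0(ifelse(loop$X >= 0, "p", "m"),
                ifelse(loop$Y >= 0, "p", "m"),
                ifelse(loop$Z >= 0, "p", "m"))
  lv <- c("ppp", "ppm", "pmp", "pmm", "mpp", "mpm", "mmp", "mmm")
  tot <- sum(w)
  degenerate <- tot <= 0
  frac <- if (degenerate) {
    rlang::set_names(rep(1 / 8, 8), lv)
  } else {
    f <- vapply(split(w, factor(key, levels = lv)), sum, numeric(1))
    f[is.na(f)] <- 0
    f / tot
  }
  out <- param_row(paste0(prefix, "_octant_", names(frac)), "octant",
                   "fraction", unname(frac))
  attr(out, "degenerate") <- degenerate
  out
}

#' Velocity parameters of the median loops
#'
#' Speed along each median loop as the finite-difference step length divided
#' by the grid time step (mV/s); reported are the maximum and mean speed per
#' loop and the R-to-T mean-speed ratio.
#'
#' @param ml A [median_loops()] object (each loop carries its `t` column).
#' @return Parameter tibble.
#' @export
velocity_params <- function(ml) {
  speeds <- purrr::imap(ml[c("P", "R", "T")], function(m, nm) {
    if (nrow(m) < 2L) stop("Single-point loop has no velocity.", call. = FALSE)
    ds <- sqrt(diff(m$X)^2 + diff(m$Y)^2 + diff(m$Z)^2)
    v <- ds / diff(m$t)
    dplyr::bind_rows(
      param_row(paste0(nm, "_speed_max"), "velocity", "mV/s", max(v)),
      param_row(paste0(nm, "_speed_mean"), "velocity", "mV/s", mean(v))
    )
  })
  tab <- dplyr::bind_rows(speeds)
  rmean <- tab$value[tab$name == "R_speed_mean"]
  tmean <- tab$value[tab$name == "T_speed_mean"]
  dplyr::bind_rows(
    tab,
    param_row("ratio_RT_speed_mean", "velocity", "1", rmean / tmean)
  )
}

circular_sd_deg <- function(theta_deg) {
  th <- theta_deg * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  deg(sqrt(-2 * log(max(R, .Machine$double.eps))))
}

#' Beat-to-beat variability parameters
#'
#' For each per-beat scalar re-computable on single-beat loops (maximum
#' vector longitude, latitude and magnitude of the R and T loops), the
#' standard deviation across beats; angles use the circular standard
#' deviation.
#'
#' @param loops A `cgm_loops` tibble (per-beat loops).
#' @param min_beats Minimum beat count, default 3.
#' @return Parameter tibble (all values >= 0).
#' @export
variability_params <- function(loops, min_beats = 3) {
  per_beat <- loops |>
    dplyr::filter(.data$loop %in% c("R", "T")) |>
    dplyr::group_by(.data$loop, .data$beat) |>
    dplyr::group_modify(function(df, key) {
      v <- max_vector(df)
      tibble::tibble(longitude = deg(atan2(v[2], v[1])),
                     latitude = deg(asin(pmin(1, pmax(-1, v[3] / vnorm(v))))),
                     magnitude = vnorm(v))
    }) |>
    dplyr::ungroup()
  n_beats <- length(unique(per_beat$beat))
  if (n_beats < min_beats) {
    stop(sprintf("Insufficient beats for variability: %d < %d.",
                 n_beats, min_beats), call. = FALSE)
  }
  per_beat |>
    dplyr::group_by(.data$loop) |>
    dplyr::summarise(
      longitude_sd = circular_sd_deg(.data$longitude),
      latitude_sd = circular_sd_deg(.data$latitude),
      magnitude_sd = stats::sd(.data$magnitude),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"loop", names_to = "what") |>
    dplyr::transmute(
      name = paste0(.data$loop, "_max_", .data$what),
      class = "variability",
      units = ifelse(grepl("magnitude", .data$name), "mV", "deg"),
      value = .data$value
    )
}

#' Extract the full parameter vector from a trajectory
#'
#' Runs the whole extraction chain — segmentation, median loops, then every
#' parameter class (angles, amplitudes, shapes, octants, velocities,
#' beat-to-beat variability) — and concatenates the results in a fixed,
#' deterministic order.
#'
#' @param traj A `vcg_trajectory`.
#' @param ann Optional [detect_beats()] annotations (detected if omitted).
#' @param config A [cgm_config()].
#' @return A `cgm_parameters` tibble `name, class, units, value`.
#' @export
extract_all <- function(traj, ann = NULL, config = cgm_config()) {
  if (is.null(ann)) ann <- detect_beats(traj, config)
  loops <- segment_loops(traj, ann)
  ml <- median_loops(loops, grid_points = config$grid_points,
                     min_beats = config$min_beats)
  shapes <- purrr::imap(ml[c("P", "R", "T")],
                        function(m, nm) shape_params(m, prefix = nm))
  octants <- purrr::imap(ml[c("P", "R", "T")],
                         function(m, nm) octant_params(m, prefix = nm))
  out <- dplyr::bind_rows(
    angle_params(ml),
    amplitude_params(ml),
    dplyr::bind_rows(shapes),
    dplyr::bind_rows(octants),
    velocity_params(ml),
    variability_params(loops, min_beats = config$min_beats)
  )
  if (anyDuplicated(out$name)) stop("Duplicate parameter names.", call. = FALSE)
  structure(out, class = c("cgm_parameters", class(tibble::tibble())))
}
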