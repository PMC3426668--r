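#' Default beat-detector and fiducial-window configuration
#'
#' Fiducial windows are fixed physiologic offsets around each detected R
#' peak (all in milliseconds, all configurable): QRS onset at `R - qrs_pre`,
#' the J point at `R + qrs_post`, the T offset at
#' `min(next R - t_guard, R + t_max)`, and the P window at
#' `R - p_start .. R - p_end`. The ST/T loop starts at the J point.
#'
#' @param bandpass Band edges (Hz) of the zero-phase 4th-order Butterworth
#'   filter applied to the vector magnitude before peak search.
#' @param threshold_frac Detection threshold as a fraction of the rolling
#'   maximum of the filtered magnitude.
#' @param rolling_window_s Width (s) of the rolling-maximum window.
#' @param refractory_ms Minimum R-R separation (ms).
#' @param qrs_pre,qrs_post QRS onset / J-point offsets from R (ms).
#' @param t_guard,t_max T-offset rule: next R minus `t_guard`, capped at
#'   R plus `t_max` (ms).
#' @param p_start,p_end P-window limits before R (ms).
#' @param min_beats Minimum number of beats required for median loops.
#' @param grid_points Number of samples of the common median-loop grid.
#' @param max_rate Heart-rate exclusion bound (bpm); faster recordings are
#'   flagged, mirroring the tachycardia exclusion of the clinical protocol.
#' @param rr_cv_warn R-R coefficient-of-variation threshold above which the
#'   recording is flagged as irregular (ectopy / atrial fibrillation are
#'   outside the validated envelope).
#' @return A list of class `cgm_config`.
#' @export
cgm_config <- function(bandpass = c(8, 40), threshold_frac = 0.5,
                       rolling_window_s = 2, refractory_ms = 250,
                       qrs_pre = 60, qrs_post = 60,
                       t_guard = 240, t_max = 450,
                       p_start = 260, p_end = 90,
                       min_beats = 3, grid_points = 120,
                       max_rate = 150, rr_cv_warn = 0.2) {
  structure(as.list(environment()), class = "cgm_config")
}

#' Detect beats and place fiducial points on a heart-vector trajectory
#'
#' R peaks are local maxima of the heart-vector magnitude after band-pass
#' filtering, subject to an adaptive threshold (a fraction of the rolling
#' 2-s maximum) and a refractory period; each peak is then refined to the
#' magnitude maximum of the unfiltered signal nearby. P, QRS and T fiducials
#' are placed by the fixed windows of [cgm_config()].
#'
#' @param traj A `vcg_trajectory`.
#' @param config A [cgm_config()].
#' @return A `cgm_annotations` tibble, one row per beat, with sample indices
#'   (1-based) `r_peak`, `p_on`, `p_off`, `qrs_on`, `j`, `t_off`, and
#'   attributes `warnings` (character) and `heart_rate` (bpm).
#' @export
detect_beats <- function(traj, config = cgm_config()) {
  stopifnot(inherits(traj, "vcg_trajectory"))
  fs <- sampling_rate(traj)
  n <- nrow(traj)
  if (n / fs < 2) stop("Recording shorter than 2 s.", call. = FALSE)
  mag <- sqrt(traj$X^2 + traj$Y^2 + traj$Z^2)
  if (max(mag) <= 0) {
    stop("No beats found: trajectory has zero magnitude.", call. = FALSE)
  }
  filt <- bandpass_magnitude(mag, fs, config$bandpass)
  env <- abs(filt)
  thr <- config$threshold_frac * rolling_max(env, round(config$rolling_window_s * fs))
  refr <- round(config$refractory_ms / 1000 * fs)
  # local maxima of the filtered envelope above threshold
  cand <- which(env >= thr & env >= c(-Inf, env[-n]) & env >= c(env[-1], -Inf))
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) == 0L || i - peaks[length(peaks)] > refr) {
      peaks <- c(peaks, i)
    } else if (env[i] > env[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  if (length(peaks) == 0L) stop("No beats found.", call. = FALSE)
  # refine to the raw-magnitude maximum within +-50 ms
  half <- round(0.05 * fs)
  half <- as.integer(half)
  peaks <- vapply(as.integer(peaks), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(mag[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # collapse refinements that merged within the refractory period
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > refr)
    peaks <- peaks[keep]
  }

  warnings <- character(0)
  hr <- NA_real_
  if (length(peaks) >= 2L) {
    rr <- diff(peaks) / fs
    hr <- 60 / stats::median(rr)
    if (hr > config$max_rate) {
      warnings <- c(warnings, sprintf(
        "heart rate %.0f bpm exceeds %g bpm exclusion bound", hr,
        config$max_rate))
    }
    if (stats::sd(rr) / mean(rr) > config$rr_cv_warn) {
      warnings <- c(warnings, "high R-R variability (> 20% CV); irregular rhythm")
    }
  }

  ms <- function(x) round(x / 1000 * fs)
  nxt <- c(peaks[-1], NA_integer_)
  t_off <- pmin(ifelse(is.na(nxt), n, nxt - ms(config$t_guard)),
                peaks + ms(config$t_max))
  ann <- tibble::tibble(
    beat   = seq_along(peaks),
    r_peak = peaks,
    p_on   = pmax(1L, peaks - ms(config$p_start)),
    p_off  = pmax(1L, peaks - ms(config$p_end)),
    qrs_on = pmax(1L, peaks - ms(config$qrs_pre)),
    j      = pmin(n, peaks + ms(config$qrs_post)),
    t_off  = as.integer(pmin(n, t_off))
  )
  structure(ann, warnings = warnings, heart_rate = hr,
            class = c("cgm_annotations", class(tibble::tibble())))
}

bandpass_magnitude <- function(mag, fs, band) {
  ny <- fs / 2
  bf <- signal::butter(4, pmin(band / ny, 0.99), type = "pass")
  # zero-phase filtering; pad to tame edge transients
  pad <- min(length(mag) - 1L, round(fs))
  x <- c(rev(mag[seq_len(pad)]), mag, rev(mag[length(mag) - seq_len(pad) + 1L]))
  y <- signal::filtfilt(bf, x)
  y[pad + seq_along(mag)]
}

rolling_max <- function(x, w) {
  n <- length(x)
  half <- max(1L, w %/% 2L)
  out <- numeric(n)
  # coarse block maxima are enough for an adaptive detection threshold
  step <- max(1L, half %/% 4L)
  anchors <- unique(c(seq(1L, n, by = step), n))
  amax <- vapply(anchors, function(i) {
    max(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  stats::approx(anchors, amax, xout = seq_len(n), rule = 2)$y
}

#' Segment a trajectory into per-beat P, R and T loops
#'
#' Slices the trajectory by the fiducials: P loop from P onset to P offset,
#' R (QRS) loop from QRS onset to the J point, T (ST/T) loop from J to the
#' T offset.
#'
#' @param traj A `vcg_trajectory`.
#' @param ann Annotations from [detect_beats()].
#' @return A `cgm_loops` tibble in long form: `beat`, `loop` (factor P/R/T),
#'   `t`, `X`, `Y`, `Z`, with the sampling rate as attribute.
#' @export
segment_loops <- function(traj, ann) {
  stopifnot(inherits(traj, "vcg_trajectory"))
  n <- nrow(traj)
  idx <- c(ann$p_on, ann$p_off, ann$qrs_on, ann$j, ann$t_off)
  if (any(idx < 1L | idx > n)) {
    stop("Annotation index outside the recording.", call. = FALSE)
  }
  one <- function(beat, from, to, label) {
    tibble::tibble(beat = beat, loop = label,
                   t = traj$t[from:to], X = traj$X[from:to],
                   Y = traj$Y[from:to], Z = traj$Z[from:to])
  }
  out <- purrr::pmap(
    list(ann$beat, ann$p_on, ann$p_off, ann$qrs_on, ann$j, ann$t_off),
    function(b, pon, poff, qon, j, toff) {
      dplyr::bind_rows(one(b, pon, poff, "P"), one(b, qon, j, "R"),
                       one(b, j, toff, "T"))
    }
  )
  out <- dplyr::bind_rows(out)
  out$loop <- factor(out$loop, levels = c("P", "R", "T"))
  structure(out, sampling_rate = sampling_rate(traj),
            class = c("cgm_loops", class(tibble::tibble())))
}

#' Median loop across beats
#'
#' Resamples each beat's loop onto a common time-normalised grid by linear
#' interpolation and takes the coordinate-wise median across beats at every
#' grid point — the noise-robust beat template on which maximum vectors are
#' measured.
#'
#' @param loops A `cgm_loops` tibble.
#' @param which One of `"P"`, `"R"`, `"T"`.
#' @param grid_points Grid length (default 120).
#' @param min_beats Minimum number of beats required (default 3).
#' @return A tibble `s, t, X, Y, Z` where `s` is the grid index and `t` the
#'   median elapsed time (s); attribute `duration` is the median loop
#'   duration.
#' @export
median_loop <- function(loops, which = c("R", "P", "T"), grid_points = 120,
                        min_beats = 3) {
  which <- match.arg(which)
  sub <- dplyr::filter(loops, .data$loop == which)
  beats <- split(sub, sub$beat)
  beats <- beats[vapply(beats, nrow, integer(1)) >= 2L]
  if (length(beats) < min_beats) {
    stop(sprintf("Insufficient beats for a median %s loop: %d < %d.",
                 which, length(beats), min_beats), call. = FALSE)
  }
  grids <- lapply(beats, function(b) {
    u <- seq(0, 1, length.out = grid_points)
    s <- (b$t - b$t[1]) / (b$t[nrow(b)] - b$t[1])
    cbind(X = stats::approx(s, b$X, u, ties = "ordered")$y,
          Y = stats::approx(s, b$Y, u, ties = "ordered")$y,
          Z = stats::approx(s, b$Z, u, ties = "ordered")$y)
  })
  arr <- array(unlist(grids), dim = c(grid_points, 3, length(grids)))
  med <- apply(arr, c(1, 2), stats::median)
  dur <- stats::median(vapply(beats, function(b) b$t[nrow(b)] - b$t[1],
                              numeric(1)))
  tibble::tibble(
    s = seq_len(grid_points),
    t = seq(0, dur, length.out = grid_points),
    X = med[, 1], Y = med[, 2], Z = med[, 3]
  ) |>
    structure(duration = dur)
}

#' Median P, R and T loops with their maximum vectors
#'
#' @param loops A `cgm_loops` tibble from [segment_loops()].
#' @param grid_points,min_beats Passed to [median_loop()].
#' @return A `cgm_median_loops` list with elements `P`, `R`, `T` (median-loop
#'   tibbles) and `max_vectors`, a tibble `loop, X, Y, Z, magnitude`.
#' @export
median_loops <- function(loops, grid_points = 120, min_beats = 3) {
  ml <- purrr::map(
    rlang::set_names(c("P", "R", "T")),
    ~median_loop(loops, .x, grid_points = grid_points, min_beats = min_beats)
  )
  mv <- purrr::imap(ml, function(m, nm) {
    v <- max_vector(m)
    tibble::tibble(loop = nm, X = v[1], Y = v[2], Z = v[3],
                   magnitude = sqrt(sum(v^2)))
  }) |> dplyr::bind_rows()
  structure(list(P = ml$P, R = ml$R, T = ml$T, max_vectors = mv),
            class = "cgm_median_loops")
}

#' @export
print.cgm_median_loops <- function(x, ...) {
  cat("<cgm_median_loops> grid", nrow(x$R), "points per loop\n")
  print(x$max_vectors)
  invisible(x)
}

#' Maximum vector of a loop
#'
#' The sampled loop point of largest Euclidean norm; ties are resolved to
#' the earliest sample.
#'
#' @param loop A data frame with columns `X`, `Y`, `Z`.
#' @return A named numeric vector `c(X, Y, Z)`.
#' @export
max_vector <- function(loop) {
  if (is.null(loop) || nrow(loop) == 0L) stop("Empty loop.", call. = FALSE)
  norms <- sqrt(loop$X^2 + loop$Y^2 + loop$Z^2)
  i <- which.max(norms)  # which.max returns the first maximum: earliest tie
  c(X = loop$X[i], Y = loop$Y[i], Z = loop$Z[i])
}
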