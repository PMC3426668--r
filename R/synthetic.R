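#' Configuration of a synthetic vectorcardiogram
#'
#' Describes a ground-truthed synthetic recording: each beat is the
#' concatenation of three planar elliptical loops (P, QRS, T), each with a
#' half-sine magnitude envelope along its maximum-vector direction and a
#' `sin(2*pi*s)` minor-axis component, so the configured maximum vector is
#' attained exactly at mid-loop (the minor/major axis ratio must stay below
#' `1/sqrt(2)` for that to be the global maximum; it is validated here).
#'
#' @param heart_rate Heart rate in bpm (30-150).
#' @param loops Tibble with one row per loop (`"P"`, `"R"`, `"T"`) and
#'   columns `loop`, `longitude` (deg, angle in the oblique-sagittal plane),
#'   `latitude` (deg, elevation toward +Z), `magnitude` (mV, maximum-vector
#'   norm), `duration_ms`, `axis_ratio` (minor/major, in \[0, 0.7\]).
#' @param st_offset Numeric length-3 ST-segment offset vector (mV), applied
#'   between the end of the QRS loop and the T-loop onset and tapered to
#'   zero across the T loop.
#' @param noise_sd Isotropic Gaussian noise SD per axis (mV).
#' @param sampling_rate Sampling rate (Hz), nominally 1000.
#' @param duration Recording duration (s), nominally 12.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A list of class `vcg_config`.
#' @export
vcg_config <- function(heart_rate = 60,
                       loops = default_loop_spec(),
                       st_offset = c(0, 0, 0),
                       noise_sd = 0,
                       sampling_rate = 1000,
                       duration = 12,
                       seed = 1L) {
  loops <- tibble::as_tibble(loops)
  stopifnot(
    all(c("loop", "longitude", "latitude", "magnitude", "duration_ms",
          "axis_ratio") %in% names(loops)),
    setequal(loops$loop, c("P", "R", "T"))
  )
  if (heart_rate < 30 || heart_rate > 150) {
    stop("`heart_rate` must lie in [30, 150] bpm.", call. = FALSE)
  }
  if (any(loops$duration_ms <= 0) || duration <= 0 || sampling_rate <= 0) {
    stop("Durations and sampling rate must be positive.", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  if (any(loops$axis_ratio < 0 | loops$axis_ratio > 0.7)) {
    stop("`axis_ratio` must lie in [0, 0.7].", call. = FALSE)
  }
  if (length(st_offset) != 3L || !is.numeric(st_offset)) {
    stop("`st_offset` must be a numeric 3-vector.", call. = FALSE)
  }
  if (is.null(seed) || is.na(seed)) {
    stop("An explicit integer `seed` is required.", call. = FALSE)
  }
  structure(list(heart_rate = heart_rate, loops = loops,
                 st_offset = as.numeric(st_offset), noise_sd = noise_sd,
                 sampling_rate = sampling_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "vcg_config")
}

#' Default loop morphology of the synthetic generator
#'
#' Magnitudes, durations and orientations chosen to resemble adult sinus
#' beats: a dominant QRS loop (1.2 mV, 100 ms), a smaller T loop (0.4 mV,
#' 250 ms) at a modest spatial angle from it, and a small P loop (0.15 mV,
#' 110 ms).
#' @return Tibble usable as the `loops` field of [vcg_config()].
#' @export
default_loop_spec <- function() {
  tibble::tribble(
    ~loop, ~longitude, ~latitude, ~magnitude, ~duration_ms, ~axis_ratio,
    "P",          35,        25,       0.15,          110,         0.4,
    "R",          20,       -15,       1.20,          100,         0.35,
    "T",          45,         5,       0.40,          250,         0.30
  )
}

#' Direction unit vector from longitude/latitude (degrees)
#' @param longitude Angle in the X-Y (oblique-sagittal) plane, `atan2(Y, X)`.
#' @param latitude Elevation toward +Z.
#' @return Unit 3-vector `c(X, Y, Z)`.
#' @export
direction_from_angles <- function(longitude, latitude) {
  lo <- longitude * pi / 180
  la <- latitude * pi / 180
  c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

loop_plane_minor_axis <- function(u) {
  a <- if (abs(u[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  v <- cross3(u, a)
  v / vnorm(v)
}

#' Generate a synthetic heart-vector recording with ground truth
#'
#' Beats are laid out with the first R peak at 0.3 s and R-R spacing
#' `60/heart_rate`; intra-beat timings (P at R-230..-120 ms, QRS centred on
#' R, T from R+150 ms) compress proportionally once R-R drops below 0.8 s.
#' Identical seeds give bit-identical output.
#'
#' @param cfg A [vcg_config()].
#' @return A list with `trajectory` (a `vcg_trajectory`), and `truth`: a
#'   list with per-beat fiducial sample indices (`beats` tibble), the
#'   configured `max_vectors` tibble, and the generating config.
#' @export
synth_vcg <- function(cfg) {
  stopifnot(inherits(cfg, "vcg_config"))
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  rr <- 60 / cfg$heart_rate
  scale <- min(1, rr / 0.8)
  r_times <- seq(0.3, by = rr, length.out = 10000)
  r_times <- r_times[r_times + 0.45 * scale <= cfg$duration]
  H <- matrix(0, n, 3)

  spec <- cfg$loops
  rowf <- function(l) spec[spec$loop == l, ]
  pR <- rowf("R"); pP <- rowf("P"); pT <- rowf("T")
  qrs_half <- pR$duration_ms / 2000 * scale

  add_loop <- function(H, t0, t1, row) {
    i0 <- max(1L, round(t0 * fs) + 1L); i1 <- min(n, round(t1 * fs) + 1L)
    if (i1 <= i0) return(H)
    s <- seq(0, 1, length.out = i1 - i0 + 1L)
    u <- direction_from_angles(row$longitude, row$latitude)
    v <- loop_plane_minor_axis(u)
    path <- row$magnitude * (sin(pi * s) %o% u) +
      row$axis_ratio * row$magnitude * (sin(2 * pi * s) %o% v)
    H[i0:i1, ] <- H[i0:i1, ] + path
    H
  }
  add_st <- function(H, t0, t1, delta, taper_from = NULL, taper_to = NULL) {
    i0 <- max(1L, round(t0 * fs) + 1L); i1 <- min(n, round(t1 * fs) + 1L)
    if (i1 <= i0) return(H)
    w <- rep(1, i1 - i0 + 1L)
    H[i0:i1, ] <- H[i0:i1, ] + w %o% delta
    H
  }

  beats <- vector("list", length(r_times))
  for (k in seq_along(r_times)) {
    tr <- r_times[k]
    p0 <- tr - 0.230 * scale; p1 <- tr - 0.120 * scale
    q0 <- tr - qrs_half;      q1 <- tr + qrs_half
    t0 <- tr + 0.150 * scale; t1 <- t0 + pT$duration_ms / 1000 * scale
    H <- add_loop(H, p0, p1, pP)
    H <- add_loop(H, q0, q1, pR)
    H <- add_loop(H, t0, t1, pT)
    if (any(cfg$st_offset != 0)) {
      # plateau over the first 60% of the ST segment, then taper to zero at
      # the T onset so the T loop itself stays uncontaminated
      knee <- q1 + 0.6 * (t0 - q1)
      H <- add_st(H, q1, knee, cfg$st_offset)
      i0 <- max(1L, round(knee * fs) + 1L); i1 <- min(n, round(t0 * fs) + 1L)
      if (i1 > i0) {
        s <- seq(0, 1, length.out = i1 - i0 + 1L)
        H[i0:i1, ] <- H[i0:i1, ] + (1 - s) %o% cfg$st_offset
      }
    }
    beats[[k]] <- tibble::tibble(
      beat = k,
      r_peak = round(tr * fs) + 1L,
      p_on = round(p0 * fs) + 1L, p_off = round(p1 * fs) + 1L,
      qrs_on = round(q0 * fs) + 1L, j = round(q1 * fs) + 1L,
      t_on = round(t0 * fs) + 1L, t_off = round(t1 * fs) + 1L
    )
  }
  if (cfg$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(cfg$seed)
    H <- H + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd), n, 3)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  traj <- as_trajectory(
    tibble::tibble(t = seq(0, by = 1 / fs, length.out = n),
                   X = H[, 1], Y = H[, 2], Z = H[, 3]),
    sampling_rate = fs
  )
  mv <- dplyr::mutate(
    spec,
    dir = purrr::map2(.data$longitude, .data$latitude, direction_from_angles)
  )
  max_vectors <- tibble::tibble(
    loop = mv$loop,
    X = purrr::map_dbl(mv$dir, 1) * mv$magnitude,
    Y = purrr::map_dbl(mv$dir, 2) * mv$magnitude,
    Z = purrr::map_dbl(mv$dir, 3) * mv$magnitude,
    magnitude = mv$magnitude
  )
  list(trajectory = traj,
       truth = list(beats = dplyr::bind_rows(beats),
                    max_vectors = max_vectors, config = cfg))
}

#' Apply an ischaemia-like perturbation to a generator configuration
#'
#' Severity acts on three morphological axes at once: the T maximum-vector
#' direction is rotated away from the R direction (in their common plane) by
#' `severity * theta_max`; the R/T magnitude ratio is increased by
#' `severity * delta_rt` (by shrinking the T magnitude); and an ST-segment
#' offset of `severity * st_max` mV is applied opposite the R direction
#' (ST-depression-like). Severity 0 returns the configuration unchanged.
#'
#' @param cfg A [vcg_config()].
#' @param severity Scalar in \[0, 1\].
#' @param theta_max Maximal added R-T spatial angle (deg), default 60.
#' @param delta_rt Maximal added R/T magnitude ratio, default 2.
#' @param st_max Maximal ST offset magnitude (mV), default 0.15.
#' @return A perturbed `vcg_config`.
#' @export
apply_ischaemia <- function(cfg, severity, theta_max = 60, delta_rt = 2,
                            st_max = 0.15) {
  stopifnot(inherits(cfg, "vcg_config"))
  if (!is.numeric(severity) || length(severity) != 1L || is.na(severity) ||
      severity < 0 || severity > 1) {
    stop("`severity` must be a scalar in [0, 1].", call. = FALSE)
  }
  if (severity == 0) return(cfg)
  loops <- cfg$loops
  iR <- which(loops$loop == "R"); iT <- which(loops$loop == "T")
  uR <- direction_from_angles(loops$longitude[iR], loops$latitude[iR])
  uT <- direction_from_angles(loops$longitude[iT], loops$latitude[iT])
  alpha <- acos(pmin(1, pmax(-1, sum(uR * uT))))
  w <- uT - sum(uT * uR) * uR
  if (vnorm(w) < 1e-9) w <- loop_plane_minor_axis(uR) else w <- w / vnorm(w)
  alpha2 <- min(alpha + severity * theta_max * pi / 180, pi - 1e-6)
  uT2 <- cos(alpha2) * uR + sin(alpha2) * w
  loops$longitude[iT] <- atan2(uT2[2], uT2[1]) * 180 / pi
  loops$latitude[iT] <- asin(pmin(1, pmax(-1, uT2[3]))) * 180 / pi
  ratio0 <- loops$magnitude[iR] / loops$magnitude[iT]
  loops$magnitude[iT] <- loops$magnitude[iR] / (ratio0 + severity * delta_rt)
  cfg$loops <- loops
  cfg$st_offset <- cfg$st_offset - severity * st_max * uR
  cfg
}

#' Specification of a synthetic diagnostic cohort
#'
#' @param n_cases,n_controls Group sizes (>= 1).
#' @param tests Tibble with columns `test`, `sensitivity`, `specificity`
#'   (probabilities).
#' @param rho Latent-severity coupling in \[0, 1\]: each patient draws one
#'   standard-normal severity; each test thresholds
#'   `sqrt(rho) * severity + sqrt(1 - rho) * noise` at the probit of its
#'   marginal positivity rate, so `rho = 0` gives conditional independence
#'   and larger `rho` makes the tests agree more than chance.
#' @param seed Integer seed (required).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, tests, rho = 0, seed = 1L) {
  tests <- tibble::as_tibble(tests)
  stopifnot(all(c("test", "sensitivity", "specificity") %in% names(tests)))
  if (any(tests$sensitivity < 0 | tests$sensitivity > 1 |
            tests$specificity < 0 | tests$specificity > 1)) {
    stop("Sensitivities and specificities must lie in [0, 1].", call. = FALSE)
  }
  if (n_cases < 1 || n_controls < 1) stop("Group sizes must be >= 1.", call. = FALSE)
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1].", call. = FALSE)
  if (is.null(seed) || is.na(seed)) stop("An explicit `seed` is required.", call. = FALSE)
  structure(list(n_cases = n_cases, n_controls = n_controls, tests = tests,
                 rho = rho, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Operating characteristics of the four admission tests
#'
#' Named fixture `"cgm_acs_table2"`: marginal sensitivity/specificity of the
#' admission ECG (0.28/0.78), first troponin (0.34/0.98), serial troponin
#' (0.50/0.96) and CGM (0.69/0.54) for detecting NSTE-ACS.
#' @param n_cases,n_controls Group sizes; default the study's 162 / 54.
#' @param rho Latent coupling, default 0.3 (the admission tests all track
#'   disease severity, so some positive dependence is the realistic case).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec_table2 <- function(n_cases = 162, n_controls = 54, rho = 0.3,
                               seed = 1L) {
  cohort_spec(
    n_cases, n_controls,
    tibble::tribble(
      ~test,              ~sensitivity, ~specificity,
      "ecg",                      0.28,         0.78,
      "troponin_first",           0.34,         0.98,
      "troponin_serial",          0.50,         0.96,
      "cgm",                      0.69,         0.54
    ),
    rho = rho, seed = seed
  )
}

#' Simulate a diagnostic cohort with specified test characteristics
#'
#' @param spec A [cohort_spec()].
#' @return A `cgm_cohort` tibble: `patient_id`, `truth`
#'   (`"case"`/`"control"`), and one `"positive"`/`"negative"` column per
#'   test.
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  truth <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  sev <- stats::rnorm(n)
  out <- tibble::tibble(patient_id = sprintf("pt%05d", seq_len(n)),
                        truth = truth)
  for (i in seq_len(nrow(spec$tests))) {
    p_pos <- ifelse(truth == "case", spec$tests$sensitivity[i],
                    1 - spec$tests$specificity[i])
    u <- sqrt(spec$rho) * sev + sqrt(1 - spec$rho) * stats::rnorm(n)
    out[[spec$tests$test[i]]] <-
      ifelse(u <= stats::qnorm(p_pos), "positive", "negative")
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(out, class = c("cgm_cohort", class(tibble::tibble())))
}

#' Deterministic cohort reproducing the study's admission-test counts
#'
#' Builds a 216-patient cohort (162 NSTE-ACS cases, 54 controls) whose
#' per-test positive counts match the published marginals exactly (ECG
#' 45/12, first troponin 55/1, serial troponin 81/2, CGM 111/25 positives
#' among cases/controls), in which a positive first troponin implies a
#' positive serial troponin, in which exactly 106 patients (65 cases, 41
#' controls) are negative on both ECG and serial troponin with CGM positive
#' in 42 of those cases and 17 of those controls, and in which 28 of the 162
#' cases are missed by both CGM and the first troponin (so the OR
#' combination detects 134/162). The full joint distribution was never
#' published; this synthetic joint is the minimal completion consistent with
#' all those published margins.
#'
#' @return A `cgm_cohort` tibble with columns `patient_id`, `truth`, `ecg`,
#'   `troponin_first`, `troponin_serial`, `cgm`, `sex`.
#' @export
cohort_table2 <- function() {
  blk <- function(n, ecg, serial, first_pos, cgm_pos) {
    # first_pos / cgm_pos are counts of positives within the block,
    # assigned to the leading rows (deterministic)
    tibble::tibble(
      ecg = rep(ecg, n),
      troponin_serial = rep(serial, n),
      troponin_first = rep(c("positive", "negative"),
                           c(first_pos, n - first_pos)),
      cgm = rep(c("positive", "negative"), c(cgm_pos, n - cgm_pos))
    )
  }
  neg <- "negative"; pos <- "positive"
  cases <- dplyr::bind_rows(
    # subgroup: ECG- and serial troponin- (65 cases; CGM+ in 42)
    blk(65, neg, neg, first_pos = 0, cgm_pos = 42),
    # ECG- serial+ (52; first troponin + in 35; CGM- in the first 20 of
    # those -> CGM+ 32): order cgm negatives first to pin the joint
    tibble::tibble(ecg = rep(neg, 52), troponin_serial = rep(pos, 52),
                   troponin_first = rep(c(pos, neg), c(35, 17)),
                   cgm = rep(c(neg, pos), c(20, 32))),
    # ECG+ serial+ (29; first+ 20, of which 3 CGM-)
    tibble::tibble(ecg = rep(pos, 29), troponin_serial = rep(pos, 29),
                   troponin_first = rep(c(pos, neg), c(20, 9)),
                   cgm = rep(c(neg, pos), c(3, 26))),
    # ECG+ serial- (16; CGM- 5)
    tibble::tibble(ecg = rep(pos, 16), troponin_serial = rep(neg, 16),
                   troponin_first = rep(neg, 16),
                   cgm = rep(c(neg, pos), c(5, 11)))
  )
  controls <- dplyr::bind_rows(
    blk(41, neg, neg, first_pos = 0, cgm_pos = 17),       # subgroup controls
    blk(1, neg, pos, first_pos = 0, cgm_pos = 1),
    blk(1, pos, pos, first_pos = 1, cgm_pos = 1),
    blk(11, pos, neg, first_pos = 0, cgm_pos = 6)
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(cases, truth = "case"),
    dplyr::mutate(controls, truth = "control")
  )
  n <- nrow(out)
  # female counts match the published 32.7 % / 40.7 % rates
  out <- tibble::tibble(
    patient_id = sprintf("pt%05d", seq_len(n)),
    truth = out$truth,
    ecg = out$ecg,
    troponin_first = out$troponin_first,
    troponin_serial = out$troponin_serial,
    cgm = out$cgm,
    sex = c(rep(c("female", "male"), c(53, 109)),
            rep(c("female", "male"), c(22, 32)))
  )
  structure(out, class = c("cgm_cohort", class(tibble::tibble())))
}
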