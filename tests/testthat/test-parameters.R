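fake_ml <- function(P, R, T) {
  mv <- purrr::imap(list(P = P, R = R, T = T), function(m, nm) {
    v <- max_vector(m)
    tibble::tibble(loop = nm, X = v[1], Y = v[2], Z = v[3],
                   magnitude = sqrt(sum(v^2)))
  }) |> dplyr::bind_rows()
  structure(list(P = P, R = R, T = T, max_vectors = mv),
            class = "cgm_median_loops")
}

line_loop <- function(u, m = 1, n = 50, t_end = 0.1) {
  s <- seq(0, 1, length.out = n)
  tibble::tibble(t = seq(0, t_end, length.out = n),
                 X = m * sin(pi * s) * u[1], Y = m * sin(pi * s) * u[2],
                 Z = m * sin(pi * s) * u[3])
}

test_that("angle parameters follow the longitude/latitude convention", {
  ml <- fake_ml(line_loop(c(0, 1, 0), 0.2),
                line_loop(c(1, 0, 0), 1.2),
                line_loop(c(0, 1, 0), 0.4))
  ang <- angle_params(ml)
  expect_equal(param_value(ang, "R_max_longitude"), 0)
  expect_equal(param_value(ang, "R_max_latitude"), 0)
  expect_equal(param_value(ang, "angle_RT"), 90)
  expect_equal(param_value(ang, "angle_PT"), 0)
  # ranges
  expect_true(all(ang$value[grepl("longitude", ang$name)] > -180 &
                    ang$value[grepl("longitude", ang$name)] <= 180))
  expect_true(all(abs(ang$value[grepl("latitude", ang$name)]) <= 90))

  zml <- fake_ml(line_loop(c(1, 0, 0)),
                 tibble::tibble(t = 0:1, X = c(0, 0), Y = 0, Z = 0),
                 line_loop(c(1, 0, 0)))
  expect_error(angle_params(zml), "zero magnitude")
})

test_that("extraction recovers configured angles on a noise-free synthetic", {
  pv <- default_params()
  cfg <- default_sim()$truth$config$loops
  uR <- direction_from_angles(cfg$longitude[cfg$loop == "R"],
                              cfg$latitude[cfg$loop == "R"])
  uT <- direction_from_angles(cfg$longitude[cfg$loop == "T"],
                              cfg$latitude[cfg$loop == "T"])
  want_rt <- acos(sum(uR * uT)) * 180 / pi
  expect_lt(abs(param_value(pv, "angle_RT") - want_rt), 2)
  expect_lt(abs(param_value(pv, "R_max_longitude") -
                  cfg$longitude[cfg$loop == "R"]), 2)
  expect_lt(abs(param_value(pv, "R_max_latitude") -
                  cfg$latitude[cfg$loop == "R"]), 2)
})

test_that("amplitudes are homogeneous of degree one, ratios invariant", {
  ml <- fake_ml(line_loop(c(0, 1, 0), 0.3), line_loop(c(1, 0, 0), 1.2),
                line_loop(c(1, 1, 1) / sqrt(3), 0.4))
  amp1 <- amplitude_params(ml)
  double <- function(m) dplyr::mutate(m, X = 2 * X, Y = 2 * Y, Z = 2 * Z)
  amp2 <- amplitude_params(fake_ml(double(ml$P), double(ml$R), double(ml$T)))
  scalers <- amp1$units == "mV"
  expect_equal(amp2$value[scalers], 2 * amp1$value[scalers], tolerance = 1e-12)
  expect_equal(amp2$value[!scalers], amp1$value[!scalers], tolerance = 1e-12)
  expect_equal(param_value(amp1, "ratio_RT_magnitude"), 3)

  # configured ST offset is recovered at J + 20 ms
  sim <- synth_vcg(vcg_config(st_offset = c(-0.1, 0, 0), seed = 31))
  pv <- extract_all(sim$trajectory)
  expect_lt(abs(param_value(pv, "ST_level") - 0.1), 0.01)
})

test_that("shape parameters match closed forms and a brute-force oracle", {
  circ <- ellipse_loop(a = 1, b = 1)
  sh <- shape_params(circ, "R")
  expect_lt(abs(param_value(sh, "R_eccentricity")), 1e-6)
  expect_equal(param_value(sh, "R_planarity"), 1)

  line <- line_loop(c(1, 2, 2) / 3)
  shl <- shape_params(line, "R")
  expect_equal(param_value(shl, "R_eccentricity"), 1)

  ell <- ellipse_loop(a = 2, b = 1)
  she <- shape_params(ell, "R")
  # brute-force principal extents: sd of projections over a fine
  # direction grid in the loop plane
  th <- seq(0, pi, length.out = 3600)
  sds <- vapply(th, function(a) {
    stats::sd(ell$X * cos(a) + ell$Y * sin(a))
  }, numeric(1))
  ecc_oracle <- sqrt(1 - (min(sds) / max(sds))^2)
  expect_lt(abs(param_value(she, "R_eccentricity") - ecc_oracle), 1e-3)
  expect_lt(abs(param_value(she, "R_eccentricity") - sqrt(1 - 0.25)), 0.01)
})

test_that("octant fractions are a probability distribution over sign cells", {
  up <- tibble::tibble(t = 1:10 / 10, X = runif(10) + 0.1,
                       Y = runif(10) + 0.1, Z = runif(10) + 0.1)
  oc <- octant_params(up, "R")
  expect_equal(param_value(oc, "R_octant_ppp"), 1)
  expect_equal(sum(oc$value), 1, tolerance = 1e-9)

  # circle in the X-Y plane at Z = +eps: four upper octants at 1/4 each
  circ <- ellipse_loop(a = 1, b = 1, n = 400, z = 1e-6)
  occ <- octant_params(circ, "R")
  expect_equal(sum(occ$value), 1, tolerance = 1e-9)
  for (cell in c("ppp", "pmp", "mpp", "mmp")) {
    expect_equal(param_value(occ, paste0("R_octant_", cell)), 0.25,
                 tolerance = 1e-6)
  }

  zero <- tibble::tibble(t = 1:4, X = 0, Y = 0, Z = 0)
  ocz <- octant_params(zero, "R")
  expect_true(attr(ocz, "degenerate"))
  expect_equal(ocz$value, rep(1 / 8, 8))
})

test_that("velocities match closed form and scale with time dilation", {
  # uniform circular loop: constant speed 2 pi r / T
  circ <- ellipse_loop(a = 0.5, b = 0.5, n = 1000, t_end = 0.2)
  ml <- fake_ml(circ, circ, circ)
  v <- velocity_params(ml)
  expect_lt(abs(param_value(v, "R_speed_mean") - 2 * pi * 0.5 / 0.2) /
              (2 * pi * 0.5 / 0.2), 0.01)
  expect_equal(param_value(v, "ratio_RT_speed_mean"), 1)

  slow <- dplyr::mutate(circ, t = 2 * t)
  v2 <- velocity_params(fake_ml(slow, slow, slow))
  expect_equal(param_value(v2, "R_speed_mean"),
               param_value(v, "R_speed_mean") / 2, tolerance = 1e-9)

  # finite-difference brute force on the extracted median QRS loop
  sim <- default_sim()
  mlr <- median_loops(segment_loops(sim$trajectory,
                                    detect_beats(sim$trajectory)))
  vv <- velocity_params(mlr)
  brute <- max(sqrt(diff(mlr$R$X)^2 + diff(mlr$R$Y)^2 + diff(mlr$R$Z)^2) /
                 diff(mlr$R$t))
  expect_equal(param_value(vv, "R_speed_max"), brute)
})

test_that("variability is zero for identical beats and tracks injected jitter", {
  u <- direction_from_angles(20, 0)
  ident <- loops_from_vectors(rep(list(u), 6))
  vb <- variability_params(ident)
  expect_true(all(vb$value < 1e-9))
  expect_true(all(vb$value >= 0))

  set.seed(77)
  lons <- 20 + rnorm(12, 0, 5)
  jit <- loops_from_vectors(lapply(lons, direction_from_angles, latitude = 0))
  vj <- variability_params(jit)
  expect_lt(abs(param_value(vj, "R_max_longitude_sd") - 5), 2)

  expect_error(variability_params(loops_from_vectors(rep(list(u), 2))),
               "Insufficient beats")
})

test_that("extract_all composes the class extractors deterministically", {
  sim <- default_sim()
  ann <- detect_beats(sim$trajectory)
  pv1 <- extract_all(sim$trajectory, ann)
  pv2 <- extract_all(sim$trajectory, ann)
  expect_identical(pv1, pv2)
  expect_false(anyDuplicated(pv1$name) > 0)
  expect_setequal(unique(pv1$class),
                  c("angle", "amplitude", "shape", "octant", "velocity",
                    "variability"))

  ml <- median_loops(segment_loops(sim$trajectory, ann))
  ang <- angle_params(ml)
  sub <- tibble::as_tibble(pv1)[pv1$name %in% ang$name, c("name", "value")]
  expect_equal(dplyr::arrange(sub, name),
               dplyr::arrange(ang[, c("name", "value")], name))
})

test_that("a 90-degree rotation about Z shifts longitudes and permutes octants", {
  sim <- default_sim()
  ann <- detect_beats(sim$trajectory)
  tr <- sim$trajectory
  rot <- as_trajectory(tibble::tibble(t = tr$t, X = -tr$Y, Y = tr$X,
                                      Z = tr$Z),
                       sampling_rate = sampling_rate(tr))
  pv <- extract_all(tr, ann)
  pvr <- extract_all(rot, ann)
  d_lon <- (param_value(pvr, "R_max_longitude") -
              param_value(pv, "R_max_longitude")) %% 360
  expect_equal(d_lon, 90, tolerance = 1e-6)
  expect_equal(param_value(pvr, "R_max_latitude"),
               param_value(pv, "R_max_latitude"), tolerance = 1e-9)
  expect_equal(param_value(pvr, "angle_RT"), param_value(pv, "angle_RT"),
               tolerance = 1e-9)
  expect_equal(param_value(pvr, "R_max_magnitude"),
               param_value(pv, "R_max_magnitude"), tolerance = 1e-9)
  expect_equal(param_value(pvr, "R_eccentricity"),
               param_value(pv, "R_eccentricity"), tolerance = 1e-9)
  expect_equal(param_value(pvr, "R_speed_max"),
               param_value(pv, "R_speed_max"), tolerance = 1e-9)
  # (x, y, z) -> (-y, x, z): octant ppp receives mass from pmp, etc.
  expect_equal(param_value(pvr, "R_octant_ppp"),
               param_value(pv, "R_octant_pmp"), tolerance = 1e-9)
  expect_equal(param_value(pvr, "R_octant_mpp"),
               param_value(pv, "R_octant_ppp"), tolerance = 1e-9)
})
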