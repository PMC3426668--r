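# Shared fixtures, built once per test run.

# default noise-free 60 bpm recording + its extracted parameters
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- synth_vcg(vcg_config(heart_rate = 60, seed = 101))
  }
  .fixture_env$sim
}

default_params <- function() {
  if (is.null(.fixture_env$params)) {
    sim <- default_sim()
    .fixture_env$params <- extract_all(sim$trajectory)
  }
  .fixture_env$params
}

param_value <- function(pv, nm) pv$value[pv$name == nm]

# a bare loop tibble (one closed planar ellipse), for direct parameter tests
ellipse_loop <- function(a = 2, b = 1, n = 2000, z = 0, t_end = 1) {
  th <- (seq_len(n) - 0.5) / n * 2 * pi
  tibble::tibble(t = seq(0, t_end, length.out = n),
                 X = a * cos(th), Y = b * sin(th), Z = rep(z, n))
}

# hand-built per-beat loop set: one R loop per beat along a given direction
loops_from_vectors <- function(dirs, magnitude = 1, loop = "R", n = 30) {
  purrr::imap(dirs, function(u, k) {
    s <- seq(0, 1, length.out = n)
    env <- magnitude * sin(pi * s)
    tibble::tibble(beat = k, loop = loop, t = s,
                   X = env * u[1], Y = env * u[2], Z = env * u[3])
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(loop = factor(loop, levels = c("P", "R", "T"))) |>
    structure(sampling_rate = 1000,
              class = c("cgm_loops", class(tibble::tibble())))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# random parameter tibble + matching ranges, for scoring contract tests
random_catalog <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(name = sprintf("p%02d", seq_len(n)),
                 class = "amplitude", units = "mV",
                 value = stats::rnorm(n))
}
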