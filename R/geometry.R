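#' Electrode geometry of the cardiogoniometric lead system
#'
#' Builds the canonical five-electrode arrangement in body coordinates.
#' Point 1 sits at the cardiac apex position (V4), point 2 sagittally behind
#' it on the back (V8), point 3 vertically above point 1 at `height_ratio`
#' times the 1-2 distance, and point 4 to the subject's right of point 3 at
#' that same distance. All coordinates are expressed in multiples of the
#' point-1 to point-2 distance `d`, so the construction is scale free. The
#' ground electrode is only the potential reference and carries no geometry.
#'
#' The body frame is right-handed with axes (posterior, cranial, right):
#' `posterior = (1,0,0)`, `cranial = (0,1,0)`, `right = (0,0,1)`.
#'
#' @param height_ratio Vertical spacing of point 3 above point 1, as a
#'   fraction of the 1-2 distance. Default 0.7, the standard placement.
#' @return An object of class `cgm_electrode_model`: a list with the four
#'   electrode `positions` (4 x 3 matrix, rows p1..p4), the body-axis unit
#'   vectors, the `height_ratio`, and the per-lead displacement vectors.
#' @examples
#' m <- electrode_model()
#' sqrt(sum((m$positions["p3", ] - m$positions["p1", ])^2))  # 0.7
#' @export
electrode_model <- function(height_ratio = 0.7) {
  if (!is.numeric(height_ratio) || length(height_ratio) != 1L ||
      !is.finite(height_ratio) || height_ratio <= 0 || height_ratio > 2) {
    stop("`height_ratio` must be a single number in (0, 2].", call. = FALSE)
  }
  posterior <- c(1, 0, 0)
  cranial   <- c(0, 1, 0)
  right     <- c(0, 0, 1)
  r <- height_ratio
  positions <- rbind(
    p1 = c(0, 0, 0),
    p2 = posterior,             # p1 + d * posterior, d = 1
    p3 = r * cranial,           # p1 + r * d * cranial
    p4 = r * cranial + r * right
  )
  # Lead displacement vectors, negative -> positive electrode. Using the
  # full displacement (not its unit) keeps the potential-difference
  # identities I = A - D and Ve = A - Ho exact in the forward model.
  leads <- rbind(
    D  = positions["p4", ] - positions["p2", ],
    A  = positions["p4", ] - positions["p1", ],
    I  = positions["p2", ] - positions["p1", ],
    Ho = positions["p4", ] - positions["p3", ],
    Ve = positions["p3", ] - positions["p1", ]
  )
  structure(
    list(positions = positions, height_ratio = r,
         posterior = posterior, cranial = cranial, right = right,
         lead_vectors = leads),
    class = "cgm_electrode_model"
  )
}

#' @export
print.cgm_electrode_model <- function(x, ...) {
  cat("<cgm_electrode_model> height_ratio =", x$height_ratio, "\n")
  print(round(x$positions, 4))
  invisible(x)
}

#' Orthonormal heart-oriented XYZ basis of an electrode model
#'
#' Derives the three orthogonal projection axes from the electrode geometry.
#' Points 4-2-1 span the oblique sagittal plane (OSP, the main plane); points
#' 4-3-1 span the frontal plane. The X axis lies in the OSP and in the
#' sagittal plane perpendicular to it (positive = posterior), Y lies in the
#' OSP and the frontal plane (positive = toward the apex, i.e. caudal /
#' anterior-left), and Z is normal to the OSP (negative = up, so positive Z
#' points inferiorly).
#'
#' @param model A [electrode_model()] object.
#' @return A `cgm_basis`: 3 x 3 matrix with rows `x`, `y`, `z` (unit vectors
#'   in body coordinates).
#' @export
derive_basis <- function(model) {
  stopifnot(inherits(model, "cgm_electrode_model"))
  p <- model$positions
  osp_n <- cross3(p["p2", ] - p["p1", ], p["p4", ] - p["p1", ])
  frontal_n <- cross3(p["p3", ] - p["p1", ], p["p4", ] - p["p1", ])
  if (vnorm(osp_n) < 1e-12 || vnorm(frontal_n) < 1e-12) {
    stop("Degenerate electrode geometry: defining points are collinear.",
         call. = FALSE)
  }
  # Z: normal to the OSP, oriented downward (negative values point up).
  z <- osp_n / vnorm(osp_n)
  if (sum(z * model$cranial) > 0) z <- -z
  # Y: intersection of OSP and frontal plane, oriented baso-apically.
  y <- cross3(osp_n, frontal_n)
  y <- y / vnorm(y)
  # Toward the apex: caudal and anterior (apex points down-forward-left).
  if (sum(y * model$cranial) > 0 || sum(y * model$posterior) > 0) y <- -y
  # X: completes the orthogonal triple inside the OSP, posterior positive.
  x <- cross3(y, z)
  x <- x / vnorm(x)
  if (sum(x * model$posterior) < 0) x <- -x
  b <- rbind(x = x, y = y, z = z)
  colnames(b) <- c("posterior", "cranial", "right")
  structure(b, class = c("cgm_basis", "matrix", "array"))
}

#' @export
print.cgm_basis <- function(x, ...) {
  cat("<cgm_basis> rows x, y, z in body coordinates\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Five cardiogoniometric leads from the four electrode potentials
#'
#' Forms the lead voltages D (dorsal, 4-2), A (anterior, 4-1), I (inferior,
#' 2-1), Ho (horizontal, 4-3) and Ve (vertical, 3-1) from the per-sample
#' electrode potentials. The identities `I = A - D` and `Ve = A - Ho` hold by
#' construction.
#'
#' @param potentials Data frame with columns `phi1`..`phi4` (mV) and
#'   optionally `t` (seconds); one row per sample.
#' @param sampling_rate Sampling rate in Hz (ignored if a `t` column with at
#'   least two samples is present, from which it is inferred).
#' @return A `cgm_leads` tibble with columns `t, D, A, I, Ho, Ve` and a
#'   `sampling_rate` attribute.
#' @export
leads_from_potentials <- function(potentials, sampling_rate = 1000) {
  potentials <- tibble::as_tibble(potentials)
  need <- c("phi1", "phi2", "phi3", "phi4")
  if (!all(need %in% names(potentials))) {
    stop("`potentials` must have columns phi1, phi2, phi3, phi4.",
         call. = FALSE)
  }
  n <- nrow(potentials)
  lens <- vapply(potentials[need], length, integer(1))
  if (length(unique(lens)) != 1L) stop("Unequal channel lengths.", call. = FALSE)
  if ("t" %in% names(potentials) && n >= 2L) {
    sampling_rate <- 1 / stats::median(diff(potentials$t))
  }
  tvec <- if ("t" %in% names(potentials)) potentials$t else
    seq(0, by = 1 / sampling_rate, length.out = n)
  new_leads(tibble::tibble(
    t  = tvec,
    D  = potentials$phi4 - potentials$phi2,
    A  = potentials$phi4 - potentials$phi1,
    I  = potentials$phi2 - potentials$phi1,
    Ho = potentials$phi4 - potentials$phi3,
    Ve = potentials$phi3 - potentials$phi1
  ), sampling_rate)
}

new_leads <- function(df, sampling_rate) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be positive.", call. = FALSE)
  }
  structure(df, sampling_rate = sampling_rate,
            class = c("cgm_leads", class(tibble::tibble())))
}

new_trajectory <- function(df, sampling_rate) {
  structure(df, sampling_rate = sampling_rate,
            class = c("vcg_trajectory", class(tibble::tibble())))
}

#' Sampling rate of a signal object
#' @param x A `cgm_leads` or `vcg_trajectory` object.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

# 5 x 3 forward matrix: lead value = h . lead displacement vector,
# h expressed in basis coordinates.
lead_matrix <- function(model, basis = derive_basis(model)) {
  model$lead_vectors %*% t(unclass(basis))
}

# 3 x 5 reconstruction matrix: per-plane least squares, then assembly.
# OSP (D, A, I) yields (X, Y); frontal (Ho, Ve, A) yields (Y, Z); the two
# Y estimates are averaged (they coincide exactly on consistent leads).
reconstruction_matrix <- function(model, basis = derive_basis(model)) {
  U <- lead_matrix(model, basis)          # rows D, A, I, Ho, Ve
  osp <- U[c("D", "A", "I"), c(1, 2)]     # in-plane components (X, Y)
  fro <- U[c("Ho", "Ve", "A"), c(2, 3)]   # in-plane components (Y, Z)
  if (qr(osp)$rank < 2 || qr(fro)$rank < 2) {
    stop("Rank-deficient lead-direction matrix; degenerate geometry.",
         call. = FALSE)
  }
  pinv <- function(M) solve(crossprod(M), t(M))
  osp_i <- pinv(osp)                      # 2 x 3, maps (D,A,I) -> (X, Y)
  fro_i <- pinv(fro)                      # 2 x 3, maps (Ho,Ve,A) -> (Y, Z)
  W <- matrix(0, 3, 5, dimnames = list(c("X", "Y", "Z"),
                                       c("D", "A", "I", "Ho", "Ve")))
  W["X", c("D", "A", "I")] <- osp_i[1, ]
  W["Y", c("D", "A", "I")] <- osp_i[2, ] / 2
  W["Y", c("Ho", "Ve", "A")] <- W["Y", c("Ho", "Ve", "A")] + fro_i[1, ] / 2
  W["Z", c("Ho", "Ve", "A")] <- fro_i[2, ]
  W
}

#' Reconstruct the 3D heart-vector trajectory from the five leads
#'
#' Recovers the heart vector for every sample by per-plane least squares:
#' the oblique-sagittal leads D, A, I determine the X and Y components, the
#' frontal leads Ho, Ve, A determine Y and Z, and the two Y estimates are
#' averaged. The map is linear and exactly inverts [forward_leads()].
#'
#' @param leads A `cgm_leads` tibble (see [leads_from_potentials()]).
#' @param model Electrode model giving the lead geometry.
#' @return A `vcg_trajectory` tibble `t, X, Y, Z` (mV) with the sampling
#'   rate carried as an attribute.
#' @export
project_to_xyz <- function(leads, model = electrode_model()) {
  stopifnot(inherits(leads, "cgm_leads"))
  W <- reconstruction_matrix(model)
  L <- as.matrix(as.data.frame(leads)[, c("D", "A", "I", "Ho", "Ve")])
  H <- L %*% t(W)
  new_trajectory(
    tibble::tibble(t = leads$t, X = H[, 1], Y = H[, 2], Z = H[, 3]),
    sampling_rate(leads)
  )
}

#' Forward-project a heart-vector trajectory onto the five leads
#'
#' Synthesises the lead voltages a given heart vector would produce under a
#' uniform lead field: each lead is the scalar product of the heart vector
#' with the displacement vector between its electrodes. The potential
#' identities `I = A - D` and `Ve = A - Ho` therefore hold exactly, and
#' [project_to_xyz()] recovers the input trajectory.
#'
#' @param traj A `vcg_trajectory` tibble `t, X, Y, Z`.
#' @param model Electrode model giving the lead geometry.
#' @return A `cgm_leads` tibble.
#' @export
forward_leads <- function(traj, model = electrode_model()) {
  stopifnot(inherits(traj, "vcg_trajectory"))
  U <- lead_matrix(model)
  H <- as.matrix(as.data.frame(traj)[, c("X", "Y", "Z")])
  L <- H %*% t(U)
  colnames(L) <- rownames(U)
  new_leads(tibble::as_tibble(cbind(tibble::tibble(t = traj$t),
                                    tibble::as_tibble(L))),
            sampling_rate(traj))
}

#' Build a trajectory object from raw XYZ samples
#'
#' @param df Data frame with columns `X`, `Y`, `Z` (mV) and optionally `t`.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `vcg_trajectory` tibble.
#' @export
as_trajectory <- function(df, sampling_rate = 1000) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("X", "Y", "Z") %in% names(df)))
  if (!all(is.finite(df$X) & is.finite(df$Y) & is.finite(df$Z))) {
    stop("Trajectory values must be finite.", call. = FALSE)
  }
  if (!"t" %in% names(df)) {
    df <- tibble::tibble(t = seq(0, by = 1 / sampling_rate,
                                 length.out = nrow(df)),
                         X = df$X, Y = df$Y, Z = df$Z)
  }
  new_trajectory(df[, c("t", "X", "Y", "Z")], sampling_rate)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))
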