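# Karplus-type back-calculation of vicinal couplings from geometry, and
# ensemble averaging over trajectories.

#' Karplus parameters
#'
#' Coefficients of the three-term Karplus relation
#' \deqn{^3J(\phi) = A\cos^2\phi + B\cos\phi + C} mapping an H-C-C-H torsion
#' to a vicinal coupling. The default `A = 7.76`, `B = -1.10`, `C = 1.40` Hz
#' is the classic proton-proton parameterisation. An optional additive
#' substituent correction `delta` (Hz) accommodates generalised,
#' electronegativity-corrected forms behind the same interface. Parameters
#' must keep `J` nonnegative over the whole circle.
#'
#' @param A,B,C coefficients in Hz; `A > 0`.
#' @param delta constant substituent correction in Hz (default 0).
#' @return list of class `karplus_parameters`.
#' @export
karplus_parameters <- function(A = 7.76, B = -1.10, C = 1.40, delta = 0) {
  if (!is.finite(A) || A <= 0) stopf("Karplus A must be positive")
  # minimum of A c^2 + B c + C + delta over c in [-1, 1]
  cand <- c(-1, 1, if (abs(-B / (2 * A)) <= 1) -B / (2 * A))
  jmin <- min(A * cand^2 + B * cand + C + delta)
  if (jmin < 0) stopf("parameters give negative J (min %.3g Hz); not physical", jmin)
  structure(list(A = A, B = B, C = C, delta = delta),
            class = "karplus_parameters")
}

#' Evaluate the Karplus relation
#'
#' @param phi torsion angle(s) in degrees; periodic with period 360.
#' @param params a [karplus_parameters] object.
#' @return coupling(s) in Hz.
#' @examples
#' karplus_j(90)    # 1.40
#' karplus_j(180)   # A - B + C = 10.26
#' @export
karplus_j <- function(phi, params = karplus_parameters()) {
  stopifnot(inherits(params, "karplus_parameters"))
  cp <- cos(deg2rad(phi))
  params$A * cp^2 + params$B * cp + params$C + params$delta
}

#' Load Karplus parameters from a JSON config
#'
#' Reads the `karplus: {A, B, C}` block of a JSON configuration file;
#' missing fields keep their defaults.
#'
#' @param path JSON file with a top-level `karplus` object.
#' @return a [karplus_parameters] object.
#' @export
load_karplus_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- x$karplus %||% x
  karplus_parameters(A = k$A %||% 7.76, B = k$B %||% -1.10,
                     C = k$C %||% 1.40, delta = k$delta %||% 0)
}

# the four H-C-C-H torsion definitions, in coupling order
J_TORSIONS <- list(
  j12 = c("H1", "C1", "C2", "H2"),
  j23 = c("H2", "C2", "C3", "H3"),
  j34 = c("H3", "C3", "C4", "H4"),
  j45 = c("H4", "C4", "C5", "H5")
)

#' Back-calculate the four ring couplings from one frame
#'
#' Evaluates the Karplus relation on the four H-C-C-H torsions
#' H1-C1-C2-H2, H2-C2-C3-H3, H3-C3-C4-H4 and H4-C4-C5-H5.
#'
#' @param frame an [atom_frame] containing C1..C5 and H1..H5.
#' @param params a [karplus_parameters] object.
#' @return a [coupling_vector()]-style named vector (Hz).
#' @export
couplings_from_frame <- function(frame, params = karplus_parameters()) {
  j <- vapply(J_TORSIONS, function(tt) {
    karplus_j(dihedral(frame, tt[1], tt[2], tt[3], tt[4]), params)
  }, numeric(1))
  stats::setNames(j, COUPLING_NAMES)
}

# vectorised torsions over an n x 3 slab quadruple; returns length-n degrees
torsion_batch <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  crossm <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- crossm(b1, b2)
  n2 <- crossm(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  m1 <- crossm(n1, b2 / b2n)
  ang <- rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2)))
  ifelse(ang <= -180, ang + 360, ang)
}

#' Ensemble-averaged couplings over many frames
#'
#' Arithmetic mean of the per-frame back-calculated coupling vectors -- the
#' linear average that corresponds to fast exchange on the J timescale and
#' underpins the population-weighted mixing model used by the fitters.
#'
#' @param frames a [ring_trajectory] or list of [atom_frame]s (at least 1).
#' @param params a [karplus_parameters] object.
#' @return named coupling vector (Hz).
#' @export
ensemble_couplings <- function(frames, params = karplus_parameters()) {
  if (inherits(frames, "ring_trajectory")) {
    if (length(frames) == 0) stopf("empty trajectory")
    slab <- lapply(c("H1", "H2", "H3", "H4", "H5", "C1", "C2", "C3", "C4", "C5"),
                   function(a) traj_atom_xyz(frames, a))
    names(slab) <- c("H1", "H2", "H3", "H4", "H5", "C1", "C2", "C3", "C4", "C5")
    if (length(frames) == 1) slab <- lapply(slab, function(m) matrix(m, nrow = 1))
    j <- vapply(J_TORSIONS, function(tt) {
      mean(karplus_j(torsion_batch(slab[[tt[1]]], slab[[tt[2]]],
                                   slab[[tt[3]]], slab[[tt[4]]]), params))
    }, numeric(1))
    return(stats::setNames(j, COUPLING_NAMES))
  }
  fl <- as_frame_list(frames)
  if (length(fl) == 0) stopf("ensemble_couplings needs at least one frame")
  per <- vapply(fl, couplings_from_frame, numeric(4), params = params)
  stats::setNames(rowMeans(per), COUPLING_NAMES)
}

#' Derive a reference set from conformer-restrained trajectories
#'
#' The per-conformer analogue of the restrained-simulation protocol: each
#' labelled trajectory (a simulation restrained to one conformer) is
#' ensemble-averaged into that conformer's reference coupling vector.
#'
#' @param labelled_trajectories named list with entries `1C4`, `2SO`, `4C1`,
#'   each a [ring_trajectory] or list of frames with at least one frame.
#' @param params a [karplus_parameters] object.
#' @return a [conformer_refs] object with provenance `"derived"`.
#' @export
derive_reference_set <- function(labelled_trajectories,
                                 params = karplus_parameters()) {
  miss <- setdiff(FIT_BASIS, names(labelled_trajectories))
  if (length(miss)) {
    stopf("missing restrained trajectory for conformer(s): %s", paste(miss, collapse = ", "))
  }
  j <- lapply(FIT_BASIS, function(l) ensemble_couplings(labelled_trajectories[[l]], params))
  conformer_refs(j[[1]], j[[2]], j[[3]], provenance = "derived")
}
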