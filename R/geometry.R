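# Ring geometry: Cremer-Pople puckering coordinates, conformer
# classification, idealised ring construction, distances, torsions and
# geometric hydrogen-bond detection.

RING_DEFAULT <- c("O5", "C1", "C2", "C3", "C4", "C5")

# Canonical Cremer-Pople positions of the three iduronate conformers under
# this package's conventions: ring atoms indexed O5,C1,...,C5 with O5 first,
# displacement phase as in cremer_pople(). theta = 0 is the 4C1 chair
# (C4 above, C1 below the mean plane), theta = 180 the 1C4 chair. phi = 150
# on the equator is the twist form with C2 displaced above and O5 below the
# plane, i.e. the 2SO skew-boat. phi is undefined at the poles.
#
# The default puckering amplitudes are typical pyranose values: ~0.57 A for
# chairs and ~0.76 A for equatorial (boat/skew-boat) forms, whose amplitude
# is characteristically larger.

#' Canonical pucker positions and default amplitudes
#'
#' The Cremer-Pople `(theta, phi)` assigned to each basis conformer, and the
#' default puckering amplitude `Q` used by [build_ideal_ring()].
#'
#' @format data.frame with columns `label`, `theta`, `phi` (degrees; `phi`
#'   `NA` at the poles) and `Q` (Angstrom).
#' @export
CANONICAL_PUCKER <- data.frame(
  label = c("4C1", "1C4", "2SO"),
  theta = c(0, 180, 90),
  phi   = c(NA, NA, 150),
  Q     = c(0.57, 0.57, 0.76),
  stringsAsFactors = FALSE
)

# side of the ring plane on which each ring proton is placed, relative to
# the local u1 x u2 normal at its carbon (u1, u2 = unit vectors to the ring
# neighbours). This fixed pattern is the idealised L-iduronate configuration:
# it makes all four H-C-C-H torsions gauche in the 1C4 chair (small J),
# H1..H4 trans-diaxial in the 4C1 chair (large J), and brings H2 and H5 into
# the short trans-ring contact in the 2SO skew-boat.
H_SIDE <- c(H1 = -1, H2 = 1, H3 = -1, H4 = 1, H5 = 1)

#' Construct an atom frame
#'
#' A frame is one snapshot of a (partial) molecule: atom names, elements and
#' Cartesian coordinates, plus the names of the six ring atoms in
#' Cremer-Pople order.
#'
#' @param names character vector of atom names (unique).
#' @param xyz numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param elements optional element symbols; guessed from the first letter
#'   of the name when omitted.
#' @param ring six ring-atom names in Cremer-Pople order; defaults to
#'   `O5, C1, C2, C3, C4, C5`.
#' @return object of class `atom_frame` (a data.frame with columns `name`,
#'   `elem`, `x`, `y`, `z` and a `ring` attribute).
#' @export
atom_frame <- function(names, xyz, elements = NULL,
                       ring = RING_DEFAULT) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 || nrow(xyz) != length(names)) {
    stopf("xyz must be a length(names) x 3 matrix")
  }
  if (anyNA(xyz) || any(!is.finite(xyz))) stopf("coordinates must be finite")
  if (anyDuplicated(names)) stopf("duplicate atom name '%s'", names[duplicated(names)][1])
  elements <- elements %||% substr(names, 1, 1)
  df <- data.frame(name = as.character(names), elem = as.character(elements),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
  miss <- setdiff(ring, df$name)
  if (length(miss)) stopf("ring atom(s) %s missing from frame", paste(miss, collapse = ", "))
  attr(df, "ring") <- ring
  class(df) <- c("atom_frame", class(df))
  df
}

frame_xyz <- function(frame, names) {
  idx <- match(names, frame$name)
  if (anyNA(idx)) {
    stopf("atom '%s' not found in frame (available: %s)",
          names[is.na(idx)][1], paste(frame$name, collapse = ", "))
  }
  m <- as.matrix(frame[idx, c("x", "y", "z")])
  rownames(m) <- names
  m
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Computes the total puckering amplitude `Q` (Angstrom), polar angle
#' `theta` (degrees, 0-180) and azimuth `phi` (degrees, 0-360) of the six
#' ring atoms, taken in the order given by the frame's `ring` attribute
#' (conventionally O5, C1, ..., C5). The mean plane is the one defined by
#' the original Cremer-Pople construction; under it a chair with the first
#' ring atom displaced towards the ring normal has `theta = 0`.
#'
#' `phi` is undefined (flagged `phi_defined = FALSE`) at the poles and for a
#' planar ring; `theta` is undefined for a planar ring (`Q = 0`).
#'
#' @param frame an [atom_frame], or a bare 6 x 3 coordinate matrix in ring
#'   order.
#' @return object of class `pucker_coords`: list with `Q`, `theta`, `phi`,
#'   `theta_defined`, `phi_defined`.
#' @export
cremer_pople <- function(frame) {
  xyz <- if (inherits(frame, "atom_frame")) {
    frame_xyz(frame, attr(frame, "ring"))
  } else {
    m <- as.matrix(frame)
    if (nrow(m) != 6 || ncol(m) != 3) stopf("expected 6 ring atoms x 3 coordinates")
    m
  }
  ctr <- colMeans(xyz)
  R <- sweep(xyz, 2, ctr)
  j <- 0:5
  Rp  <- colSums(R * sin(2 * pi * j / 6))
  Rpp <- colSums(R * cos(2 * pi * j / 6))
  n <- cross3(Rp, Rpp)
  nn <- vnorm(n)
  if (nn < 1e-10) stopf("degenerate ring geometry: atoms are collinear")
  n <- n / nn
  z <- as.numeric(R %*% n)

  q2c <-  sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  Q <- sqrt(q2^2 + q3^2)

  planar <- Q < 1e-8
  theta <- if (planar) NA_real_ else rad2deg(atan2(q2, q3))
  phi_defined <- !planar && q2 > 1e-8
  phi <- if (phi_defined) rad2deg(atan2(q2s, q2c)) %% 360 else NA_real_
  structure(list(Q = Q, theta = theta, phi = phi,
                 theta_defined = !planar, phi_defined = phi_defined),
            class = "pucker_coords")
}

#' @export
print.pucker_coords <- function(x, ...) {
  cat(sprintf("Cremer-Pople: Q = %.3f A, theta = %s, phi = %s\n",
              x$Q,
              if (x$theta_defined) sprintf("%.1f deg", x$theta) else "undefined",
              if (x$phi_defined) sprintf("%.1f deg", x$phi) else "undefined"))
  invisible(x)
}

#' Classify a pucker as 1C4, 2SO, 4C1 or OTHER
#'
#' Assigns the nearest canonical form: `4C1` near the north pole
#' (`theta = 0`), `1C4` near the south pole (`theta = 180`), and `2SO` on
#' the equator at the canonical azimuth (see [CANONICAL_PUCKER]). Geometries
#' outside all tolerance wells, or with amplitude `Q < 0.1` Angstrom
#' (effectively planar), are `OTHER`.
#'
#' @param p a `pucker_coords` object from [cremer_pople()].
#' @param theta_tol,phi_tol half-widths of the acceptance wells, degrees.
#'   The defaults (35 and 30) are half the spacing between canonical forms.
#' @return one of `"1C4"`, `"2SO"`, `"4C1"`, `"OTHER"`.
#' @export
classify_conformer <- function(p, theta_tol = 35, phi_tol = 30) {
  stopifnot(inherits(p, "pucker_coords"))
  if (p$Q < 0.1 || !p$theta_defined) return("OTHER")
  th <- p$theta
  if (th <= theta_tol) return("4C1")
  if (th >= 180 - theta_tol) return("1C4")
  if (abs(th - 90) <= theta_tol && p$phi_defined) {
    canon_phi <- CANONICAL_PUCKER$phi[CANONICAL_PUCKER$label == "2SO"]
    dphi <- abs(((p$phi - canon_phi + 180) %% 360) - 180)
    if (dphi <= phi_tol) return("2SO")
  }
  "OTHER"
}

#' Build an idealised iduronate ring at a canonical pucker
#'
#' Places the six ring atoms O5, C1..C5 on the Cremer-Pople surface at the
#' canonical `(theta, phi)` of `label` with standard bond lengths (C-C 1.52,
#' C-O 1.43 Angstrom; the ring radius is chosen by least squares over the
#' six bonds). Ring protons H1..H5 are placed tetrahedrally (C-H 1.10
#' Angstrom) on the ring face given by the idealised L-iduronate
#' configuration (`H_SIDE` pattern). Applying [cremer_pople()] to the result
#' recovers `(Q, theta, phi)` exactly.
#'
#' @param label one of `"1C4"`, `"2SO"`, `"4C1"`.
#' @param Q puckering amplitude in Angstrom, in (0.3, 0.8). Defaults to the
#'   per-form amplitude in [CANONICAL_PUCKER] (0.57 for chairs, 0.76 for the
#'   skew-boat).
#' @param include_protons place the five ring protons? Default `TRUE`.
#' @return an [atom_frame] with 11 atoms (6 when `include_protons = FALSE`).
#' @examples
#' ring <- build_ideal_ring("2SO")
#' interproton_distance(ring, "H2", "H5")  # ~2.6 Angstrom
#' @export
build_ideal_ring <- function(label, Q = NULL, include_protons = TRUE) {
  row <- CANONICAL_PUCKER[CANONICAL_PUCKER$label == label, ]
  if (nrow(row) != 1) {
    stopf("cannot build an ideal ring for label '%s' (must be 1C4, 2SO or 4C1)", label)
  }
  Q <- Q %||% row$Q
  if (Q <= 0.3 || Q >= 0.8) stopf("Q = %.3g A is outside the supported range (0.3, 0.8)", Q)
  theta <- row$theta
  phi <- if (is.na(row$phi)) 0 else row$phi

  jj <- 0:5
  sig <- 2 * pi * jj / 6
  q2 <- Q * sin(deg2rad(theta))
  q3 <- Q * cos(deg2rad(theta))
  # out-of-plane displacements along the CP normal
  zeta <- sqrt(1 / 3) * q2 * cos(deg2rad(phi) + 2 * sig) +
    sqrt(1 / 6) * q3 * (-1)^jj

  # ring radius: least-squares match of the six bond lengths
  target <- c(1.43, 1.52, 1.52, 1.52, 1.52, 1.43)  # O5-C1, C1-C2, ..., C5-O5
  dz <- zeta[c(2:6, 1)] - zeta
  r <- stats::optimize(function(r) sum((sqrt(r^2 + dz^2) - target)^2),
                       c(0.5, 3))$minimum
  # with atoms on a circle traversed counter-clockwise the CP normal points
  # along -z, so coordinates use -zeta to realise displacement +zeta
  xyz <- cbind(r * cos(sig), r * sin(sig), -zeta)
  names <- RING_DEFAULT
  elems <- c("O", rep("C", 5))

  if (include_protons) {
    H <- matrix(0, 5, 3)
    for (k in 1:5) {
      Cat <- xyz[k + 1, ]
      prev <- xyz[k, ]
      nxt <- xyz[(k + 1) %% 6 + 1, ]
      u1 <- (prev - Cat) / vnorm(prev - Cat)
      u2 <- (nxt - Cat) / vnorm(nxt - Cat)
      b <- -(u1 + u2); b <- b / vnorm(b)
      w <- cross3(u1, u2); w <- w / vnorm(w)
      # exocyclic direction at the tetrahedral angle from both ring bonds
      cg <- cos(deg2rad(109.47)) / sum(b * u1)
      g <- acos(min(max(cg, -1), 1))
      d <- b * cos(g) + H_SIDE[k] * w * sin(g)
      H[k, ] <- Cat + 1.10 * d
    }
    xyz <- rbind(xyz, H)
    names <- c(names, paste0("H", 1:5))
    elems <- c(elems, rep("H", 5))
  }
  atom_frame(names, xyz, elements = elems)
}

#' Euclidean distance between two named atoms
#'
#' @param frame an [atom_frame].
#' @param a,b atom names.
#' @return distance in Angstrom.
#' @export
interproton_distance <- function(frame, a, b) {
  m <- frame_xyz(frame, c(a, b))
  if (identical(a, b)) return(0)
  vnorm(m[1, ] - m[2, ])
}

#' Signed torsion angle of four named atoms
#'
#' IUPAC convention: looking along b -> c, the angle from the a-b bond to
#' the c-d bond, positive clockwise; result in (-180, 180].
#'
#' @param frame an [atom_frame].
#' @param a,b,c,d atom names of the four distinct atoms.
#' @return torsion angle in degrees.
#' @export
dihedral <- function(frame, a, b, c, d) {
  nm <- c(a, b, c, d)
  if (anyDuplicated(nm)) stopf("dihedral needs four distinct atoms")
  m <- frame_xyz(frame, nm)
  torsion_xyz(m[1, ], m[2, ], m[3, ], m[4, ])
}

torsion_xyz <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stopf("degenerate torsion: three consecutive atoms are collinear")
  }
  m1 <- cross3(n1, b2 / vnorm(b2))
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Geometric hydrogen-bond criteria
#'
#' Default thresholds are common molecular-dynamics practice: heavy-atom
#' (donor-acceptor) distance at most 3.5 Angstrom and D-H...A angle at least
#' 135 degrees.
#'
#' @param max_heavy_distance donor-acceptor cutoff, Angstrom (> 0).
#' @param min_dha_angle minimum D-H...A angle, degrees, in (0, 180].
#' @param donors data.frame with columns `heavy` and `hydrogen` naming each
#'   donor's heavy atom and its proton (`hydrogen = NA` puts that donor in
#'   distance-only mode).
#' @param acceptors character vector of acceptor atom names.
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_heavy_distance = 3.5, min_dha_angle = 135,
                           donors, acceptors) {
  if (max_heavy_distance <= 0) stopf("max_heavy_distance must be positive")
  if (min_dha_angle <= 0 || min_dha_angle > 180) stopf("min_dha_angle must be in (0, 180]")
  if (missing(donors) || NROW(donors) == 0) stopf("at least one donor is required")
  if (missing(acceptors) || length(acceptors) == 0) stopf("at least one acceptor is required")
  donors <- as.data.frame(donors, stringsAsFactors = FALSE)
  if (!all(c("heavy", "hydrogen") %in% names(donors))) {
    stopf("donors needs columns 'heavy' and 'hydrogen'")
  }
  structure(list(max_heavy_distance = max_heavy_distance,
                 min_dha_angle = min_dha_angle,
                 donors = donors, acceptors = acceptors),
            class = "hbond_criteria")
}

#' Detect geometric hydrogen bonds in one frame
#'
#' Reports every donor-acceptor pair satisfying both the heavy-atom distance
#' cutoff and (when the donor proton is available) the D-H...A angle cutoff.
#' Donors whose `hydrogen` is `NA`, or absent from the frame, are evaluated
#' on distance alone (the angle is reported `NA`).
#'
#' @param frame an [atom_frame].
#' @param criteria an [hbond_criteria] object.
#' @return data.frame with columns `donor`, `acceptor`, `distance`, `angle`.
#' @export
detect_hbonds <- function(frame, criteria) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  out <- data.frame(donor = character(), acceptor = character(),
                    distance = numeric(), angle = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(criteria$donors))) {
    dheavy <- criteria$donors$heavy[i]
    dh <- criteria$donors$hydrogen[i]
    if (!dheavy %in% frame$name) stopf("donor atom '%s' not in frame", dheavy)
    for (acc in criteria$acceptors) {
      if (identical(acc, dheavy)) next
      if (!acc %in% frame$name) stopf("acceptor atom '%s' not in frame", acc)
      dist <- interproton_distance(frame, dheavy, acc)
      if (dist > criteria$max_heavy_distance) next
      ang <- NA_real_
      if (!is.na(dh) && dh %in% frame$name) {
        m <- frame_xyz(frame, c(dheavy, dh, acc))
        v1 <- m[1, ] - m[2, ]   # H -> D
        v2 <- m[3, ] - m[2, ]   # H -> A
        ang <- rad2deg(acos(min(max(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)), -1), 1)))
        if (ang < criteria$min_dha_angle) next
      }
      out <- rbind(out, data.frame(donor = dheavy, acceptor = acc,
                                   distance = dist, angle = ang,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Hydrogen-bond occupancy over a frame sequence
#'
#' Fraction of frames in which the given donor-acceptor pair satisfies the
#' criteria.
#'
#' @param frames list of [atom_frame] objects (or a `ring_trajectory`).
#' @param criteria an [hbond_criteria] object.
#' @param donor,acceptor heavy-atom names of the pair of interest.
#' @return occupancy in \[0, 1\].
#' @export
hbond_occupancy <- function(frames, criteria, donor, acceptor) {
  frames <- as_frame_list(frames)
  if (length(frames) == 0) stopf("no frames supplied")
  hits <- vapply(frames, function(f) {
    hb <- detect_hbonds(f, criteria)
    any(hb$donor == donor & hb$acceptor == acceptor)
  }, logical(1))
  mean(hits)
}
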