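# Cremer-Pople analysis, classification, ideal rings, distances, torsions
# and hydrogen-bond detection.

hexagon <- function(z = rep(0, 6), r = 1.45) {
  ang <- 2 * pi * (0:5) / 6
  cbind(r * cos(ang), r * sin(ang), z)
}

test_that("Cremer-Pople handles the planar ring and ideal chairs", {
  flat <- cremer_pople(hexagon())
  expect_equal(flat$Q, 0, tolerance = 1e-12)
  expect_false(flat$theta_defined)
  expect_false(flat$phi_defined)

  # alternating +q/-q displacements starting positive at the first atom:
  # a perfect chair with theta at a pole and Q = sqrt(6) * q
  q <- 0.25
  up <- cremer_pople(hexagon(z = q * c(1, -1, 1, -1, 1, -1)))
  expect_equal(up$Q, sqrt(6) * q, tolerance = 1e-9)
  expect_false(up$phi_defined)
  down <- cremer_pople(hexagon(z = -q * c(1, -1, 1, -1, 1, -1)))
  expect_equal(sort(c(up$theta, down$theta)), c(0, 180), tolerance = 1e-6)
  # mirror symmetry: inverting the displacements flips the pole
  expect_equal(up$theta + down$theta, 180, tolerance = 1e-6)

  expect_error(cremer_pople(cbind(1:6, 2 * (1:6), 3 * (1:6))), "collinear")
})

test_that("Cremer-Pople coordinates are invariant under rigid motion", {
  set.seed(42)
  for (label in c("1C4", "2SO", "4C1")) {
    f <- build_ideal_ring(label)
    ref <- cremer_pople(f)
    for (k in 1:5) {
      g <- rigid_transform(f, rand_rotation(), t = stats::rnorm(3, sd = 10))
      cp <- cremer_pople(g)
      expect_equal(cp$Q, ref$Q, tolerance = 1e-6)
      expect_equal(cp$theta, ref$theta, tolerance = 1e-6)
      if (ref$phi_defined) expect_equal(cp$phi, ref$phi, tolerance = 1e-6)
      # distances are invariant too
      expect_equal(interproton_distance(g, "H2", "H5"),
                   interproton_distance(f, "H2", "H5"), tolerance = 1e-9)
    }
  }
})

test_that("classification wells behave as documented", {
  mk <- function(Q, theta, phi) {
    structure(list(Q = Q, theta = theta, phi = phi,
                   theta_defined = TRUE, phi_defined = !is.na(phi)),
              class = "pucker_coords")
  }
  expect_equal(classify_conformer(mk(0.57, 5, 123)), "4C1")
  expect_equal(classify_conformer(mk(0.57, 176, 10)), "1C4")
  expect_equal(classify_conformer(mk(0.76, 90, 150)), "2SO")
  expect_equal(classify_conformer(mk(0.76, 90, 330)), "OTHER")  # opposite azimuth
  expect_equal(classify_conformer(mk(0.76, 90, 150 + 31)), "OTHER")
  expect_equal(classify_conformer(mk(0.05, 90, 150)), "OTHER")  # sub-threshold amplitude
})

test_that("ideal rings round-trip through pucker analysis and classify back", {
  for (label in c("1C4", "2SO", "4C1")) {
    row <- CANONICAL_PUCKER[CANONICAL_PUCKER$label == label, ]
    f <- build_ideal_ring(label)
    cp <- cremer_pople(f)
    expect_equal(cp$Q, row$Q, tolerance = 0.02)
    expect_equal(cp$theta, row$theta, tolerance = 1)
    if (!is.na(row$phi)) expect_equal(cp$phi, row$phi, tolerance = 1)
    expect_equal(classify_conformer(cp), label)
  }
  expect_error(build_ideal_ring("OTHER"), "OTHER")
  expect_error(build_ideal_ring("1C4", Q = 0.9), "range")
  expect_equal(nrow(build_ideal_ring("2SO", include_protons = FALSE)), 6)
})

test_that("ideal-ring H2-H5 distances reproduce the conformer fingerprint", {
  d <- vapply(c("2SO", "1C4", "4C1"), function(l) {
    interproton_distance(build_ideal_ring(l), "H2", "H5")
  }, numeric(1))
  expect_equal(d[["2SO"]], 2.6, tolerance = 0.15 / 2.6)
  expect_equal(d[["1C4"]], 4.0, tolerance = 0.2 / 4.0)
  expect_equal(d[["4C1"]], 4.2, tolerance = 0.2 / 4.2)
  # the skew-boat contact is far shorter than either chair; the idealised
  # chairs are mirror images so their distances are equal, not ordered
  expect_lt(d[["2SO"]], d[["1C4"]])
  expect_lte(d[["1C4"]], d[["4C1"]])
})

test_that("interproton_distance is a metric on named atoms", {
  f <- atom_frame(c(RING_NAMES <- c("O5", "C1", "C2", "C3", "C4", "C5"), "X", "Y"),
                  rbind(hexagon(), c(0, 0, 0), c(3, 4, 0)))
  expect_equal(interproton_distance(f, "X", "Y"), 5)
  expect_equal(interproton_distance(f, "Y", "X"), 5)
  expect_equal(interproton_distance(f, "X", "X"), 0)
  expect_error(interproton_distance(f, "X", "Z"), "not found")
})

test_that("dihedral follows the IUPAC sign convention and matches bio3d", {
  # planar cis / trans
  base <- rbind(c(-1.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0))
  cis  <- atom_frame(paste0("A", 1:4), rbind(base, c(3, 1, 0)),
                     ring = character(0))
  trans <- atom_frame(paste0("A", 1:4), rbind(base, c(3, -1, 0)),
                      ring = character(0))
  expect_equal(dihedral(cis, "A1", "A2", "A3", "A4"), 0, tolerance = 1e-9)
  expect_equal(abs(dihedral(trans, "A1", "A2", "A3", "A4")), 180, tolerance = 1e-9)

  # staggered butane-like geometry built analytically at +/-60 degrees
  for (tau in c(60, -60, 145)) {
    p4 <- c(2.0, cos(tau * pi / 180), sin(tau * pi / 180))
    f <- atom_frame(paste0("A", 1:4),
                    rbind(c(-0.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0), p4),
                    ring = character(0))
    got <- dihedral(f, "A1", "A2", "A3", "A4")
    # independent oracle: bio3d's torsion on the same coordinates
    oracle <- bio3d::torsion.xyz(as.numeric(t(rbind(c(-0.5, 1, 0), c(0, 0, 0),
                                                    c(1.5, 0, 0), p4))))
    expect_equal(abs(got), abs(tau), tolerance = 1e-6)
    expect_equal(abs(got), abs(oracle), tolerance = 1e-4)
    # torsion is invariant under full atom-order reversal
    expect_equal(dihedral(f, "A4", "A3", "A2", "A1"), got, tolerance = 1e-9)
  }

  degen <- atom_frame(paste0("A", 1:4),
                      rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      ring = character(0))
  expect_error(dihedral(degen, "A1", "A2", "A3", "A4"), "collinear")
  expect_error(dihedral(degen, "A1", "A2", "A2", "A4"), "distinct")
})

test_that("hydrogen bonds respect distance and angle thresholds", {
  # donor O-H pointing at an acceptor 2.8 A away, nearly linear
  mk <- function(acc_xyz, h_xyz = c(0.97, 0, 0)) {
    atom_frame(c("OD", "HD", "OA"), rbind(c(0, 0, 0), h_xyz, acc_xyz),
               elements = c("O", "H", "O"), ring = character(0))
  }
  crit <- hbond_criteria(donors = data.frame(heavy = "OD", hydrogen = "HD"),
                         acceptors = "OA")
  near_linear <- mk(c(2.8, 0.1, 0))
  hit <- detect_hbonds(near_linear, crit)
  expect_equal(nrow(hit), 1)
  expect_gt(hit$angle, 135)

  expect_equal(nrow(detect_hbonds(mk(c(5, 0, 0)), crit)), 0)        # too far
  expect_equal(nrow(detect_hbonds(mk(c(0.5, 2.75, 0)), crit)), 0)   # ~90 deg at H

  # distance-only mode when the proton is unknown
  crit2 <- hbond_criteria(donors = data.frame(heavy = "OD", hydrogen = NA),
                          acceptors = "OA")
  hit2 <- detect_hbonds(mk(c(0.5, 2.75, 0)), crit2)
  expect_equal(nrow(hit2), 1)
  expect_true(is.na(hit2$angle))

  expect_error(hbond_criteria(donors = data.frame(), acceptors = "OA"), "donor")

  # occupancy over a sequence: bonded in 1 of 2 frames
  frames <- list(near_linear, mk(c(5, 0, 0)))
  expect_equal(hbond_occupancy(frames, crit, "OD", "OA"), 0.5)
})
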