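# A lightweight container for many frames sharing one topology, plus PDB
# input/output through bio3d.

#' Construct a ring trajectory
#'
#' A trajectory is a stack of frames over a fixed atom topology, stored as
#' an `n_frames x n_atoms x 3` array. Geometry operations that average over
#' ensembles ([ensemble_couplings()], [pucker_table()]) accept either a
#' trajectory or a plain list of [atom_frame]s.
#'
#' @param names atom names (shared by all frames).
#' @param coords numeric array `n_frames x length(names) x 3`.
#' @param elements optional element symbols.
#' @param ring six ring-atom names in Cremer-Pople order.
#' @return object of class `ring_trajectory`.
#' @export
ring_trajectory <- function(names, coords, elements = NULL,
                            ring = RING_DEFAULT) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[2] != length(names) || dim(coords)[3] != 3) {
    stopf("coords must be an n_frames x n_atoms x 3 array")
  }
  miss <- setdiff(ring, names)
  if (length(miss)) stopf("ring atom(s) %s missing from trajectory", paste(miss, collapse = ", "))
  structure(list(names = as.character(names),
                 elements = elements %||% substr(names, 1, 1),
                 ring = ring, coords = coords),
            class = "ring_trajectory")
}

#' @export
length.ring_trajectory <- function(x) dim(x$coords)[1]

#' Extract one frame of a trajectory
#'
#' @param traj a [ring_trajectory].
#' @param i frame index.
#' @return an [atom_frame].
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "ring_trajectory"))
  n <- dim(traj$coords)[1]
  if (i < 1 || i > n) stopf("frame index %d out of range 1..%d", i, n)
  atom_frame(traj$names, traj$coords[i, , , drop = TRUE],
             elements = traj$elements, ring = traj$ring)
}

as_frame_list <- function(x) {
  if (inherits(x, "ring_trajectory")) {
    lapply(seq_len(length(x)), function(i) get_frame(x, i))
  } else if (inherits(x, "atom_frame")) {
    list(x)
  } else {
    as.list(x)
  }
}

# n_frames x 3 coordinate slab for one named atom
traj_atom_xyz <- function(traj, name) {
  idx <- match(name, traj$names)
  if (is.na(idx)) stopf("atom '%s' not found in trajectory", name)
  traj$coords[, idx, , drop = FALSE][, 1, ]
}

#' @export
print.ring_trajectory <- function(x, ...) {
  cat(sprintf("ring_trajectory: %d frames, %d atoms (%s)\n",
              length(x), length(x$names), paste(x$names, collapse = " ")))
  invisible(x)
}

#' Read ring frames from a PDB file
#'
#' Parses a single- or multi-MODEL PDB file (via `bio3d::read.pdb`) and
#' returns the frames as a [ring_trajectory]. Coordinate records are
#' pre-validated so that a malformed line is reported with its line number.
#'
#' @param path PDB file.
#' @param ring six ring-atom names in Cremer-Pople order; must resolve to
#'   unique atoms in the file.
#' @return a [ring_trajectory].
#' @export
read_ring_frames <- function(path, ring = RING_DEFAULT) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  at <- grep("^(ATOM  |HETATM)", lines)
  for (i in at) {
    coords <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stopf("PDB parse error at line %d of %s: bad coordinate field", i, path)
    }
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stopf("PDB parse error in %s: %s", path, conditionMessage(e)))
  names <- pdb$atom$elety
  miss <- setdiff(ring, names)
  if (length(miss)) {
    stopf("ring atom(s) %s not found in %s; available atoms: %s",
          paste(miss, collapse = ", "), path, paste(unique(names), collapse = ", "))
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nat <- length(names)
  coords <- array(NA_real_, c(nrow(xyz), nat, 3))
  for (m in seq_len(nrow(xyz))) {
    coords[m, , ] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  }
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(names), 1, 1)
  }
  ring_trajectory(names, coords, elements = trimws(elem), ring = ring)
}

#' Write frames to a (multi-MODEL) PDB file
#'
#' Each frame becomes one MODEL; atoms are written as HETATM-free ATOM
#' records through `bio3d::write.pdb`.
#'
#' @param frames a [ring_trajectory] or list of [atom_frame]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path) {
  fl <- as_frame_list(frames)
  if (length(fl) == 0) stopf("no frames to write")
  names <- fl[[1]]$name
  elem <- fl[[1]]$elem
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(fl) > 1
  for (m in seq_along(fl)) {
    f <- fl[[m]]
    if (!identical(f$name, names)) stopf("all frames must share one topology")
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    tmp <- tempfile(fileext = ".pdb")
    nat <- nrow(f)
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(t(as.matrix(f[, c("x", "y", "z")]))),
                     elety = f$name, resid = rep("RNG", nat),
                     resno = rep(1L, nat), eleno = seq_len(nat),
                     chain = rep("A", nat), o = rep(1, nat), b = rep(0, nat),
                     elesy = f$elem)
    body <- grep("^ATOM|^HETATM", readLines(tmp, warn = FALSE), value = TRUE)
    unlink(tmp)
    writeLines(body, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
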