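# Domain types: conformer labels, coupling vectors, reference sets,
# population vectors, and the bundled eight-hexasaccharide measurement table.

#' Conformer labels used throughout the package
#'
#' The iduronate pyranose ring interconverts between the \eqn{^1C_4} chair,
#' the \eqn{^2S_O} skew-boat and (rarely) the \eqn{^4C_1} chair. `"OTHER"` is
#' used by the pucker classifier for geometries outside all three canonical
#' wells; it is never part of a fit basis.
#'
#' @format character vector of length 4: `"1C4"`, `"2SO"`, `"4C1"`, `"OTHER"`.
#' @export
CONFORMERS <- c("1C4", "2SO", "4C1", "OTHER")

# the three fit-basis conformers, in canonical order
FIT_BASIS <- c("1C4", "2SO", "4C1")

COUPLING_NAMES <- c("j12", "j23", "j34", "j45")

#' Construct and validate a vector of four vicinal couplings
#'
#' Holds the four three-bond proton-proton couplings of an iduronate ring:
#' \eqn{^3J_{H1-H2}}, \eqn{^3J_{H2-H3}}, \eqn{^3J_{H3-H4}},
#' \eqn{^3J_{H4-H5}}, in Hz. Values must be finite and within the physical
#' range for vicinal H-H couplings, 0 to 15 Hz.
#'
#' @param j12,j23,j34,j45 couplings in Hz. Alternatively pass a single
#'   numeric vector of length 4 as `j12`.
#' @return named numeric vector of length 4 (`j12`, `j23`, `j34`, `j45`).
#' @examples
#' coupling_vector(2.2, 4.3, 3.2, 2.2)
#' @export
coupling_vector <- function(j12, j23, j34, j45) {
  if (missing(j23) && length(j12) == 4) {
    x <- as.numeric(j12)
  } else {
    x <- c(j12, j23, j34, j45)
  }
  if (length(x) != 4) stopf("a coupling vector has exactly 4 entries, got %d", length(x))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stopf("couplings must be finite numbers")
  }
  bad <- which(x < 0 | x > 15)
  if (length(bad)) {
    stopf("coupling %s = %.3g Hz is outside the physical range [0, 15] Hz",
          COUPLING_NAMES[bad[1]], x[bad[1]])
  }
  stats::setNames(x, COUPLING_NAMES)
}

#' Per-conformer reference couplings (the mixing basis)
#'
#' A reference set maps each of the three basis conformers to its mean
#' coupling vector. Ensemble-averaged couplings of a flipping ring are then a
#' population-weighted mixture of these rows, which is what the fitters
#' invert.
#'
#' @param c1c4,c2so,c4c1 coupling vectors (Hz) for the pure \eqn{^1C_4},
#'   \eqn{^2S_O} and \eqn{^4C_1} conformers.
#' @param provenance free-text tag recording where the values came from.
#' @return object of class `conformer_refs`: a 3 x 4 numeric matrix with rows
#'   `1C4`, `2SO`, `4C1` and columns `j12` ... `j45`, plus a `provenance`
#'   attribute.
#' @seealso [builtin_reference_set()], [load_reference_set()],
#'   [derive_reference_set()]
#' @export
conformer_refs <- function(c1c4, c2so, c4c1, provenance = "user") {
  m <- rbind(`1C4` = coupling_vector(c1c4),
             `2SO` = coupling_vector(c2so),
             `4C1` = coupling_vector(c4c1))
  for (i in 1:2) for (j in (i + 1):3) {
    if (all(abs(m[i, ] - m[j, ]) < 1e-9)) {
      stopf("reference vectors for %s and %s are identical; the mixture fit would be degenerate",
            FIT_BASIS[i], FIT_BASIS[j])
    }
  }
  attr(m, "provenance") <- as.character(provenance)
  class(m) <- c("conformer_refs", class(m))
  m
}

#' The built-in iduronate reference couplings
#'
#' Mean couplings of the three pure conformers of the IdoA/IdoA2S ring,
#' obtained from microsecond restrained molecular-dynamics ensembles (one
#' simulation per conformer) of the hexasaccharides analysed by this package:
#' \tabular{lcccc}{
#'   \tab j12 \tab j23 \tab j34 \tab j45 \cr
#'   1C4 \tab 1.35 \tab 2.04 \tab 2.19 \tab 1.69 \cr
#'   2SO \tab 5.55 \tab 8.48 \tab 4.82 \tab 3.14 \cr
#'   4C1 \tab 7.85 \tab 8.03 \tab 8.50 \tab 5.08
#' }
#' All population fits that reproduce the published measurement table use
#' this basis.
#'
#' @return a [conformer_refs] object.
#' @export
builtin_reference_set <- function() {
  conformer_refs(c(1.35, 2.04, 2.19, 1.69),
                 c(5.55, 8.48, 4.82, 3.14),
                 c(7.85, 8.03, 8.50, 5.08),
                 provenance = "builtin")
}

#' Load a reference set from JSON (or return the built-in one)
#'
#' The JSON layout has top-level keys `1C4`, `2SO`, `4C1`, each an array of
#' four Hz values, and an optional `provenance` string.
#'
#' @param source `"builtin"` or the path to a JSON file.
#' @return a [conformer_refs] object.
#' @export
load_reference_set <- function(source = "builtin") {
  if (identical(source, "builtin")) return(builtin_reference_set())
  if (!file.exists(source)) stopf("reference file not found: %s", source)
  x <- jsonlite::read_json(source, simplifyVector = TRUE)
  for (key in FIT_BASIS) {
    if (is.null(x[[key]])) stopf("reference file %s lacks the required '%s' entry", source, key)
  }
  conformer_refs(x[["1C4"]], x[["2SO"]], x[["4C1"]],
                 provenance = x[["provenance"]] %||% source)
}

#' Write a reference set to JSON
#'
#' @param refs a [conformer_refs] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(refs, path) {
  stopifnot(inherits(refs, "conformer_refs"))
  x <- list(`1C4` = unname(refs["1C4", ]),
            `2SO` = unname(refs["2SO", ]),
            `4C1` = unname(refs["4C1", ]),
            provenance = attr(refs, "provenance"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate (and optionally renormalise) a population vector
#'
#' A population vector holds the fractions of the `1C4`, `2SO` and `4C1`
#' conformers. Components must be nonnegative and sum to 1; when the sum is
#' off by no more than `tol` the vector is renormalised, beyond that it is an
#' error.
#'
#' @param p numeric vector of length 3, in the order `1C4`, `2SO`, `4C1`.
#' @param tol tolerated deviation of `sum(p)` from 1 before renormalising
#'   fails. Defaults to `1e-9`.
#' @return named, validated (possibly renormalised) population vector.
#' @examples
#' validate_population(c(0.68, 0.32, 0))
#' validate_population(c(0.334, 0.333, 0.333), tol = 1e-2)
#' @export
validate_population <- function(p, tol = 1e-9) {
  if (tol < 0) stopf("tol must be nonnegative")
  p <- as.numeric(p)
  if (length(p) != 3) stopf("a population vector has exactly 3 entries (1C4, 2SO, 4C1)")
  if (anyNA(p) || any(!is.finite(p))) stopf("populations must be finite")
  if (any(p < 0)) stopf("population of %s is negative (%.4g)",
                        FIT_BASIS[which(p < 0)[1]], min(p))
  if (abs(sum(p) - 1) > tol) {
    stopf("populations sum to %.6g, not 1 (tolerance %.3g)", sum(p), tol)
  }
  stats::setNames(p / sum(p), FIT_BASIS)
}

#' Read a measurement table of hexasaccharide couplings
#'
#' Reads a TSV or CSV table with header
#' `id, residue, j12, j23, j34, j45, noe_ratio`; `noe_ratio` (the measured
#' NOE H2-H5/H4-H5 cross-peak volume ratio) may be blank or absent. Any
#' additional columns (e.g. sulphation flags) are carried through untouched
#' as metadata.
#'
#' @param path input file; the delimiter is inferred from the header line.
#' @return data.frame with one row per hexasaccharide record, in file order.
#' @export
load_measurements <- function(path) {
  if (!file.exists(path)) stopf("measurement table not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) {
    warning("empty measurement table: ", path, call. = FALSE)
    return(empty_measurements())
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = TRUE)
  if (nrow(df) == 0) {
    warning("measurement table has a header but no rows: ", path, call. = FALSE)
    return(empty_measurements())
  }
  need <- c("id", "residue", COUPLING_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("measurement table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) {
    stopf("duplicate record id '%s' in %s", df$id[duplicated(df$id)][1], path)
  }
  for (cn in c(COUPLING_NAMES, intersect("noe_ratio", names(df)))) {
    raw <- df[[cn]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(trimws(raw)) & is.na(val))
    if (length(bad)) {
      stopf("non-numeric value '%s' in column %s, row %d of %s",
            raw[bad[1]], cn, bad[1], path)
    }
    df[[cn]] <- val
  }
  if (!"noe_ratio" %in% names(df)) df$noe_ratio <- NA_real_
  for (i in seq_len(nrow(df))) coupling_vector(as.numeric(df[i, COUPLING_NAMES]))
  df
}

empty_measurements <- function() {
  data.frame(id = character(), residue = character(),
             j12 = numeric(), j23 = numeric(), j34 = numeric(), j45 = numeric(),
             noe_ratio = numeric(), stringsAsFactors = FALSE)
}

#' Write a measurement table
#'
#' Inverse of [load_measurements()]; numeric fields round-trip exactly at
#' the default 15 significant digits.
#'
#' @param df measurement data.frame.
#' @param path output file; written as TSV.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled eight-hexasaccharide measurement table
#'
#' Measured couplings (and NOE H2-H5/H4-H5 ratios) of the IdoA2S residue in
#' hexasaccharides 1-4 and the IdoA residue in hexasaccharides 5-8, as
#' printed in the published measurement table. Sulphation flags of the
#' neighbouring residues are carried as metadata columns (`nsulfo`,
#' `sulfo6`, `sulfo3`: N-, 6-O- and 3-O-sulphation; compounds 1 and 5 carry
#' an N-unsubstituted glucosamine instead of N-sulphation).
#'
#' @return data.frame with 8 rows.
#' @export
table1_measurements <- function() {
  df <- data.frame(
    id      = as.character(1:8),
    residue = rep(c("IdoA2S", "IdoA"), each = 4),
    j12     = c(2.2, 2.2, 3.0, 3.7, 3.0, 3.1, 2.3, 2.3),
    j23     = c(4.3, 4.3, 5.8, 7.4, 5.2, 5.3, 4.3, 3.9),
    j34     = c(3.2, 3.2, 3.6, 4.0, 3.5, 3.5, 3.4, 3.5),
    j45     = c(2.2, 2.3, 2.7, 3.1, 2.7, 2.7, 2.4, 2.2),
    noe_ratio = c(0.19, 0.21, 0.26, 0.34, 0.34, 0.35, 0.22, 0.19),
    nsulfo  = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    sulfo6  = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    sulfo3  = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  df
}

#' Materialise the bundled fixture on disk
#'
#' Writes the eight-row measurement table (TSV) and the built-in reference
#' set (JSON) to `dir` and returns both in a list. Used by the analysis
#' scripts and tests; the same files ship under `inst/extdata/`.
#'
#' @param dir output directory, or `NULL` to skip writing.
#' @return list with elements `measurements` (data.frame), `refs`
#'   ([conformer_refs]) and, when `dir` is given, `paths`.
#' @export
make_table1_fixture <- function(dir = NULL) {
  meas <- table1_measurements()
  refs <- builtin_reference_set()
  out <- list(measurements = meas, refs = refs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mp <- file.path(dir, "table1_measurements.tsv")
    rp <- file.path(dir, "table1_reference.json")
    write_measurements(meas, mp)
    write_reference_set(refs, rp)
    out$paths <- c(measurements = mp, refs = rp)
  }
  out
}
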