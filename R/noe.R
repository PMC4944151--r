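# NOE H2-H5/H4-H5 ratio prediction for a conformer ensemble.

#' NOE reference data for the three conformers
#'
#' Per-conformer pure H2-H5/H4-H5 cross-peak volume ratios and the
#' inter-proton distances behind them. Defaults: pure ratios 0.05 (1C4),
#' 0.53 (2SO) and 0.03 (4C1); H2-H5 distances 4.0, 2.6 and 4.2 Angstrom.
#' The H4-H5 distance changes little between conformers; the default values
#' (2.43, 2.34, 2.35 Angstrom) are back-solved from the pure ratios and the
#' H2-H5 distances via the r^-6 two-spin relation and are derived constants,
#' not measurements.
#'
#' @param pure_ratios named numeric (`1C4`, `2SO`, `4C1`), all > 0.
#' @param h2h5 named H2-H5 distances in Angstrom, all > 1.5.
#' @param h4h5 named H4-H5 distances in Angstrom, or `NULL` to back-solve
#'   from `pure_ratios` and `h2h5`.
#' @return list of class `noe_refs` with elements `pure_ratios`, `h2h5`,
#'   `h4h5`.
#' @export
noe_reference_set <- function(pure_ratios = c(`1C4` = 0.05, `2SO` = 0.53, `4C1` = 0.03),
                              h2h5 = c(`1C4` = 4.0, `2SO` = 2.6, `4C1` = 4.2),
                              h4h5 = NULL) {
  pure_ratios <- pure_ratios[FIT_BASIS]
  h2h5 <- h2h5[FIT_BASIS]
  if (anyNA(pure_ratios) || any(pure_ratios <= 0)) stopf("pure ratios must be positive for all of 1C4, 2SO, 4C1")
  if (anyNA(h2h5) || any(h2h5 <= 1.5)) stopf("H2-H5 distances must exceed 1.5 Angstrom")
  if (is.null(h4h5)) {
    # r45 = r25 * ratio^(1/6) inverts ratio = (r45/r25)^-6... note the pure
    # ratio is (r25^-6)/(r45^-6) = (r45/r25)^6
    h4h5 <- h2h5 * pure_ratios^(1 / 6)
  } else {
    h4h5 <- h4h5[FIT_BASIS]
  }
  if (anyNA(h4h5) || any(h4h5 <= 1.5)) stopf("H4-H5 distances must exceed 1.5 Angstrom")
  structure(list(pure_ratios = pure_ratios, h2h5 = h2h5, h4h5 = h4h5),
            class = "noe_refs")
}

#' Load NOE reference overrides from a JSON config
#'
#' Reads the `noe: {pure_ratios: {...}, distances: {h2h5: ..., h4h5: ...}}`
#' block; anything omitted keeps its default.
#'
#' @param path JSON file.
#' @return a [noe_reference_set()] object.
#' @export
load_noe_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- x$noe %||% x
  def <- noe_reference_set()
  noe_reference_set(
    pure_ratios = unlist(n$pure_ratios) %||% def$pure_ratios,
    h2h5 = unlist(n$distances$h2h5) %||% def$h2h5,
    h4h5 = unlist(n$distances$h4h5)
  )
}

#' Predict the NOE ratio by linear mixing of pure ratios
#'
#' Population-weighted mean of the pure-conformer H2-H5/H4-H5 ratios.
#'
#' @param p population vector.
#' @param refs a `noe_refs` object.
#' @return dimensionless predicted ratio.
#' @examples
#' predict_ratio_linear(c(0, 1, 0))  # pure 2SO: 0.53
#' @export
predict_ratio_linear <- function(p, refs = noe_reference_set()) {
  stopifnot(inherits(refs, "noe_refs"))
  p <- validate_population(p)
  sum(p * refs$pure_ratios)
}

#' Predict the NOE ratio by r^-6 intensity averaging
#'
#' Isotropic two-spin intensity averaging: each cross-peak volume is the
#' population-weighted mean of the conformers' r^-6 intensities, and the
#' prediction is their quotient
#' \deqn{\frac{\sum_i p_i\, r_{25,i}^{-6}}{\sum_i p_i\, r_{45,i}^{-6}}.}
#'
#' @param p population vector.
#' @param refs a `noe_refs` object carrying both distances for every
#'   populated conformer.
#' @return dimensionless predicted ratio.
#' @export
predict_ratio_r6 <- function(p, refs = noe_reference_set()) {
  stopifnot(inherits(refs, "noe_refs"))
  p <- validate_population(p)
  need <- p > 0
  if (any(need & (is.na(refs$h2h5) | is.na(refs$h4h5)))) {
    stopf("missing inter-proton distance for a populated conformer")
  }
  sum(p * refs$h2h5^-6) / sum(p * refs$h4h5^-6)
}

#' Concordance between predicted and measured NOE ratio orderings
#'
#' For a set of records with fitted populations and measured ratios,
#' computes both NOE predictors and reports the Kendall rank concordance of
#' each with the measured ratios, plus the Kendall trend of each series
#' against record order (useful when records are ordered by increasing
#' sulphation).
#'
#' @param records_with_fits data.frame with columns `p_1C4`, `p_2SO`,
#'   `p_4C1` and `noe_ratio` (e.g. a [report_table()] result); at least two
#'   rows with measured ratios.
#' @param refs a `noe_refs` object.
#' @return list with `predicted_linear`, `predicted_r6`, `measured`,
#'   `tau_linear`, `tau_r6` (concordance with measurements) and
#'   `trend_linear`, `trend_r6`, `trend_measured` (Kendall tau against
#'   record order).
#' @export
ratio_trend <- function(records_with_fits, refs = noe_reference_set()) {
  df <- as.data.frame(records_with_fits)
  need <- c("p_1C4", "p_2SO", "p_4C1", "noe_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("records lack column(s): %s", paste(miss, collapse = ", "))
  df <- df[!is.na(df$noe_ratio), , drop = FALSE]
  if (nrow(df) < 2) stopf("need at least two records with measured NOE ratios")
  pl <- vapply(seq_len(nrow(df)), function(i) {
    predict_ratio_linear(c(df$p_1C4[i], df$p_2SO[i], df$p_4C1[i]), refs)
  }, numeric(1))
  pr <- vapply(seq_len(nrow(df)), function(i) {
    predict_ratio_r6(c(df$p_1C4[i], df$p_2SO[i], df$p_4C1[i]), refs)
  }, numeric(1))
  ord <- seq_len(nrow(df))
  kt <- function(x, y) suppressWarnings(stats::cor(x, y, method = "kendall"))
  list(predicted_linear = pl, predicted_r6 = pr, measured = df$noe_ratio,
       tau_linear = kt(pl, df$noe_ratio), tau_r6 = kt(pr, df$noe_ratio),
       trend_linear = kt(ord, pl), trend_r6 = kt(ord, pr),
       trend_measured = kt(ord, df$noe_ratio))
}
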