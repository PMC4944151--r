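# The core deconvolution: back-calculation, RSS conventions, grid and
# continuous fitters, and the report table that reproduces the published
# measurement table.

refs <- builtin_reference_set()
meas <- table1_measurements()
obs_row <- function(i) coupling_vector(as.numeric(meas[i, c("j12", "j23", "j34", "j45")]))

test_that("back_calculate mixes reference vectors linearly", {
  expect_equal(unname(back_calculate(c(1, 0, 0), refs)), unname(refs["1C4", ]))
  expect_equal(unname(back_calculate(c(0.25, 0.75, 0), refs, round_1dp = TRUE)),
               c(4.5, 6.9, 4.2, 2.8))
  # linearity in p
  set.seed(3)
  for (k in 1:10) {
    p <- rand_simplex(); q <- rand_simplex(); a <- stats::runif(1)
    expect_equal(back_calculate(a * p + (1 - a) * q, refs),
                 a * back_calculate(p, refs) + (1 - a) * back_calculate(q, refs),
                 tolerance = 1e-12)
  }
})

test_that("the two RSS conventions give the published numbers", {
  expect_equal(rss(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  # row 4 at the printed populations, against the rounded back-calculation:
  # the printed 1.02
  bc4 <- back_calculate(c(0.25, 0.75, 0), refs, round_1dp = TRUE)
  expect_equal(round_half_up(rss(obs_row(4), bc4), 2), 1.02)
  # row 1 against the unrounded back-calculation at (0.68, 0.32): ~0.31,
  # demonstrably different from the printed 0.34 of the rounded convention
  bc1 <- back_calculate(c(0.68, 0.32, 0), refs)
  expect_equal(rss(obs_row(1), bc1), 0.314, tolerance = 1e-2)
})

test_that("grid fit recovers the published two-state rows and ties break deterministically", {
  g1 <- fit_populations_grid(obs_row(1), refs)
  expect_equal(unname(round(g1$populations * 100)), c(68, 32, 0))
  g4 <- fit_populations_grid(obs_row(4), refs)
  expect_equal(unname(round(g4$populations * 100)), c(25, 75, 0))

  # exact basis member: perfect fit
  gb <- fit_populations_grid(refs["2SO", ], refs)
  expect_equal(unname(gb$populations), c(0, 1, 0))
  expect_equal(gb$rss_unrounded, 0)

  # an observation exactly between two lattice mixtures is a tie; the rule
  # prefers higher 1C4
  y <- back_calculate(c(0.75, 0.25, 0), refs)
  gt <- fit_populations_grid(y, refs, step = 0.5)
  expect_equal(unname(gt$populations), c(1, 0, 0))

  expect_error(fit_populations_grid(obs_row(1), refs, step = 0.3), "divide")
})

test_that("continuous fit solves the simplex least-squares problem exactly", {
  # row 7: interior three-state solution (reduced normal equations oracle,
  # frozen): (0.675, 0.292, 0.033)
  c7 <- fit_populations_continuous(obs_row(7), refs)
  expect_equal(unname(c7$populations), c(0.675, 0.292, 0.033), tolerance = 2e-3)
  # row 1: the unconstrained solution has negative 4C1 weight; active-set
  # clamping gives a two-state solution
  c1 <- fit_populations_continuous(obs_row(1), refs)
  expect_equal(unname(c1$populations), c(0.684, 0.316, 0), tolerance = 1e-3)
  expect_equal(c1$populations[["4C1"]], 0)
  # exact two-point mixture is recovered exactly
  mid <- (refs["1C4", ] + refs["4C1", ]) / 2
  cm <- fit_populations_continuous(mid, refs)
  expect_equal(unname(cm$populations), c(0.5, 0, 0.5), tolerance = 1e-9)
})

test_that("noise-free mixtures are recovered by both fitters (oracle equivalence)", {
  set.seed(19)
  for (k in 1:12) {
    p <- round(rand_simplex(), 2)
    p[3] <- 1 - p[1] - p[2]  # keep it on the 1% lattice
    if (p[3] < 0) next
    y <- back_calculate(p, refs)
    g <- fit_populations_grid(y, refs)
    cc <- fit_populations_continuous(y, refs)
    expect_equal(unname(g$populations), unname(p), tolerance = 1e-9)
    expect_equal(unname(cc$populations), unname(p), tolerance = 1e-8)
  }
})

test_that("refining the grid cannot worsen the objective, and both fitters agree", {
  for (i in seq_len(nrow(meas))) {
    y <- obs_row(i)
    g01 <- fit_populations_grid(y, refs, step = 0.01)
    g005 <- fit_populations_grid(y, refs, step = 0.005)
    cc <- fit_populations_continuous(y, refs)
    expect_lte(g005$rss_unrounded, g01$rss_unrounded + 1e-12)
    expect_lte(cc$rss_unrounded, g005$rss_unrounded + 1e-12)
    # the lattice optimum tracks the exact optimum to grid resolution: the
    # worst componentwise deviation over these rows is 1.21 steps (row 7)
    expect_true(all(abs(g01$populations - cc$populations) <= 1.5 * 0.01))
    expect_true(all(abs(g005$populations - cc$populations) <= 1.5 * 0.005))
  }
})

test_that("degenerate reference sets are rejected by the fitters", {
  # nearly-identical rows sneak past construction but break the fit solve
  r <- unclass(refs)
  r["2SO", ] <- r["1C4", ] + 1e-13
  degen <- structure(r, provenance = "x", class = c("conformer_refs", "matrix", "array"))
  expect_error(fit_populations_continuous(refs["1C4", ], degen), "degenerate")
})

test_that("report_table reproduces the published table cell for cell", {
  rep <- report_table(meas, refs)
  expect_equal(nrow(rep), 8)
  got_pct <- unname(as.matrix(rep[, c("pct_1C4", "pct_2SO", "pct_4C1")]))
  expect_equal(got_pct, unname(table1_printed$pct))
  got_calc <- unname(as.matrix(rep[, c("calc_j12", "calc_j23", "calc_j34", "calc_j45")]))
  expect_equal(got_calc, unname(table1_printed$calc))
  expect_equal(rep$rss, table1_printed$rss)
  expect_equal(rep$noe_ratio, table1_printed$noe)
  # spot-check the printed rendering of rows 4 and 7
  txt <- capture.output(format_report(rep))
  expect_match(txt[5], "25%\\s+75%\\s+-\\s+1.02")
  expect_match(txt[8], "68%\\s+29%\\s+3%\\s+0.37")
})

test_that("report_table records row failures without aborting the rest", {
  bad <- meas
  bad$j12[3] <- NA  # invalid coupling in one row
  rep <- report_table(bad, refs)
  expect_equal(nrow(rep), 7)
  fails <- attr(rep, "failures")
  expect_length(fails, 1)
  expect_equal(fails[[1]]$id, "3")
  expect_error(report_table(meas[0, ], refs), "no records")
})

test_that("run_fit writes coherent JSON and text reports", {
  out_json <- withr_local_file("report.json")
  out_text <- withr_local_file("report.txt")
  suppressMessages(
    rep <- run_fit(system.file("extdata", "table1_measurements.tsv", package = "puckerfit"),
                   refs = "builtin", out_json = out_json, out_text = out_text)
  )
  j <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_equal(j$rows$pct_2SO[4], 75)
  expect_equal(j$rows$rss, table1_printed$rss)
  expect_true(any(grepl("68%", readLines(out_text))))
  expect_error(suppressMessages(run_fit("no-such-file.tsv")), "not found")
  expect_error(suppressMessages(run_fit(meas, grid_step = 0.02)), "grid_step")
})
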