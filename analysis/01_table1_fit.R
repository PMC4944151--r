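#!/usr/bin/env Rscript
# Fit the conformer populations of the IdoA2S/IdoA residue in the eight
# hexasaccharides from their measured vicinal couplings, and write the full
# report (populations, back-calculated couplings, RSS) to results/.

suppressPackageStartupMessages(library(puckerfit))
dir.create("results", showWarnings = FALSE)

meas <- table1_measurements()
rep <- suppressMessages(
  run_fit(meas, refs = "builtin", grid_step = 0.01,
          out_json = "results/table1_report.json",
          out_text = "results/table1_report.txt")
)

cat("Conformer populations of the iduronate residue, eight hexasaccharides\n")
cat("(exact simplex least-squares against the built-in reference couplings)\n\n")
format_report(rep)

cat("\nFindings:\n")
cat(sprintf(" - low-sulphation IdoA2S (records 1-2): 1C4-dominant (%d%%)\n",
            rep$pct_1C4[1]))
cat(sprintf(" - fully sulphated IdoA2S (record 4): 2SO reaches %d%%\n",
            rep$pct_2SO[4]))
cat(sprintf(" - IdoA series: 2SO falls from %d%% (record 5) to %d%% (record 8),\n",
            rep$pct_2SO[5], rep$pct_2SO[8]))
cat(sprintf("   with a minor 4C1 component appearing in records 7 (%d%%) and 8 (%d%%)\n",
            rep$pct_4C1[7], rep$pct_4C1[8]))
cat(sprintf(" - worst printed-convention RSS: %.2f Hz^2 (record %s)\n",
            max(rep$rss), rep$id[which.max(rep$rss)]))
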