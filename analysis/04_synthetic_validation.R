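#!/usr/bin/env Rscript
# End-to-end validation on synthetic data: simulate a seeded ring-flip
# ensemble with known stationary populations, map it to jittered idealised
# geometry, derive a reference set from per-conformer restrained
# trajectories, back-calculate ensemble couplings, and check that the fit
# recovers the generating populations.

suppressPackageStartupMessages(library(puckerfit))
dir.create("results", showWarnings = FALSE)

seed <- 1
n_frames <- 50000
jitter <- 0.05

scenarios <- list(c(0.68, 0.32, 0), c(0.25, 0.75, 0), c(0.50, 0.40, 0.10))

restrained <- lapply(c(`1C4` = "1C4", `2SO` = "2SO", `4C1` = "4C1"), function(l) {
  states_to_frames(rep(l, 4000), jitter_sd = jitter,
                   seed = seed + match(l, c("1C4", "2SO", "4C1")))
})
drefs <- derive_reference_set(restrained)

rows <- lapply(seq_along(scenarios), function(s) {
  p <- scenarios[[s]]
  model <- flip_model(p, mean_dwell = 50, seed = seed + 10 * s)
  states <- simulate_flip_trajectory(model, n_frames)
  traj <- states_to_frames(states, jitter_sd = jitter, seed = seed + 10 * s + 1)
  fit <- fit_populations_continuous(ensemble_couplings(traj), drefs)
  data.frame(scenario = s,
             true_1C4 = p[1], true_2SO = p[2], true_4C1 = p[3],
             fit_1C4 = round(fit$populations[[1]], 3),
             fit_2SO = round(fit$populations[[2]], 3),
             fit_4C1 = round(fit$populations[[3]], 3),
             max_abs_err = round(max(abs(fit$populations - p)), 3))
})
res <- do.call(rbind, rows)
write.csv(res, "results/synthetic_validation.csv", row.names = FALSE)

cat(sprintf("Synthetic ring-flip recovery (%d frames, %.2f A jitter, dwell 50, seed %d)\n\n",
            n_frames, jitter, seed))
print(res, row.names = FALSE)
cat(sprintf("\nAll scenarios recover their stationary populations within %.1f points.\n",
            100 * max(res$max_abs_err)))
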