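#!/usr/bin/env Rscript
# Stage 6: planted-driver recovery experiments.
#
# Monte-Carlo check that the detector pipeline recovers known drivers:
# 20 seeded 200x200 replicates with TWI planted as the dominant single
# factor (all interactions zero), and 20 with a pure TWI x Pre_1
# interaction planted. Writes results/recovery.csv.

library(treelineq)

dir.create("results", showWarnings = FALSE)
res <- run_recovery_experiments(n_reps = 20L, seed = 0L)
write.csv(res, "results/recovery.csv", row.names = FALSE)
cat("Recovery experiments (20 replicates each):\n")
cat(sprintf("  planted dominant factor (TWI):        top-q hit rate %.0f %%\n",
            100 * res$rate[res$experiment == "planted_factor"]))
int <- res[res$experiment == "planted_interaction", ]
cat(sprintf("  planted TWI x Pre_1 interaction:      top-pair hit rate %.0f %%\n",
            100 * int$rate))
cat(sprintf("  ... with category nonlinear-enhance:  %.0f %%\n",
            100 * int$category_hits / int$n_reps))
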