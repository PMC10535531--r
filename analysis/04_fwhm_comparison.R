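#!/usr/bin/env Rscript
# Stage 4: does a narrower 8 nm FWHM beat the nominal 12 nm?
#
# Runs the Full-configuration water-leaving retrieval at 12 and 8 nm FWHM
# on the same simulated waters and reports the per-product metric deltas.
# No ordering is asserted: the table reports differences only.

library(cyanospec)

cfg <- experiment_config(
  n_waters = 3000, seed = 20260920, fwhm = c(12, 8),
  train = train_config(max_epochs = 100)
)
res <- compare_fwhm(cfg)

dir.create("results", showWarnings = FALSE)
utils::write.csv(res$table, "results/04_fwhm_metrics.csv", row.names = FALSE)
utils::write.csv(res$deltas, "results/04_fwhm_deltas.csv", row.names = FALSE)

cat("Per-product metrics at each FWHM:\n")
print(res$table[, c("product", "fwhm", "r2", "mape_percent", "rmsele")],
      digits = 3)
cat("\nDeltas (8 nm minus 12 nm):\n")
print(res$deltas, digits = 3)
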