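#!/usr/bin/env Rscript
# Stage 2: the full retrieval and band-selection sweep.
#
# For each product (Chl-a, PC, CAR) and data type (RRS, TOAR, BRR): trains
# the Full 100-channel MLP retrieval, computes the per-channel permutation
# attribution profile on the holdout, derives the nine-band (P1) and
# three-band (P2) configurations, retrains on those, and tabulates R^2,
# MAPE and RMSELE for all three configurations. Artifacts land under
# results/02_experiment/.

library(cyanospec)

cfg <- experiment_config(
  n_waters = 3000, seed = 20260920,
  train = train_config(max_epochs = 100),
  out_dir = "results/02_experiment"
)
res <- run_experiment(cfg)

cat("\nHoldout metrics (R^2 on the model target scale):\n")
print(res$metrics, digits = 3)

for (p in c("chl_a", "pc", "car")) {
  m <- res$metrics[res$metrics$product == p & res$metrics$data_type == "RRS", ]
  cat(sprintf(
    "%s (RRS): Full R2=%.2f; P1 within %.3f of Full; P2 MAPE %.0f%% vs P1 %.0f%%\n",
    p, m$r2[m$config == "Full"],
    m$r2[m$config == "Full"] - m$r2[m$config == "P1"],
    m$mape_percent[m$config == "P2"], m$mape_percent[m$config == "P1"]
  ))
}
cat("\nSelected band sets (RRS):\n")
for (key in grep("RRS", names(res$selections), value = TRUE)) {
  cat(sprintf("  %-16s %s\n", key,
              paste(round(res$selections[[key]]$centers), collapse = ", ")))
}
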