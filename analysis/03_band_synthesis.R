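#!/usr/bin/env Rscript
# Stage 3: synthesis of the minimum-viable and optimal configurations.
#
# Merges the per-product three-band (P2) selections into the minimum-viable
# configuration and the nine-band (P1) selections into the optimal
# configuration, per data type -- first from the published CyanoSat
# reference sets (exactly reproducing the published synthesis table), then
# from the emulated selections of stage 2 when available.

library(cyanospec)

dir.create("results", showWarnings = FALSE)

cat("Minimum-viable synthesis from the published P2 sets:\n")
published <- lapply(c(TOAR = "TOAR", BRR = "BRR", RRS = "RRS"), function(dt) {
  m <- merge_configs(unname(reference_selections("P2", dt)),
                     name = paste0("minimum_viable_", dt))
  cat(sprintf("  %-5s (%d bands): %s\n", dt, length(m$centers),
              paste(m$centers, collapse = ", ")))
  m
})
write_selection_csv(unname(published), "results/03_published_min_viable.csv")
writeLines(selection_markdown(unname(published)),
           "results/03_published_min_viable.md")

optimal_pub <- lapply(c(TOAR = "TOAR", BRR = "BRR", RRS = "RRS"), function(dt) {
  merge_configs(unname(reference_selections("P1", dt)), tol_nm = 0,
                name = paste0("optimal_", dt))
})
cat("\nOptimal synthesis from the published P1 sets:\n")
for (dt in names(optimal_pub)) {
  cat(sprintf("  %-5s: %d distinct bands\n", dt,
              length(optimal_pub[[dt]]$centers)))
}
write_selection_csv(unname(optimal_pub), "results/03_published_optimal.csv")

sel_path <- "results/02_experiment/selections.csv"
if (file.exists(sel_path)) {
  cat("\nEmulated synthesis (from stage 2 selections): see",
      "results/02_experiment/merged_configs.csv\n")
} else {
  cat("\nRun analysis/02_retrieval_experiment.R for the emulated synthesis.\n")
}
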