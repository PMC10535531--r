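#!/usr/bin/env Rscript
# Stage 1: generate the emulated labeled dataset.
#
# Draws 3,000 simulated waters from the seven-type mixture and emits, per
# water, one water-leaving reflectance spectrum plus top-of-atmosphere and
# bottom-of-Rayleigh spectra under two randomized atmospheres (15,000
# records). Writes a label summary and a small sample of spectra; the full
# dataset is regenerated deterministically by later stages from the seed.

library(cyanospec)

n_waters <- 3000
seed <- 20260920
dir.create("results", showWarnings = FALSE)

ds <- generate_dataset(n_waters, seed = seed)
print(ds)

rrs_meta <- ds$meta[ds$meta$data_type == "RRS", ]
summary_tbl <- do.call(rbind, lapply(split(rrs_meta, rrs_meta$water_type),
  function(d) data.frame(
    water_type = d$water_type[1], n = nrow(d),
    chl_med = stats::median(d$chl_a), chl_max = max(d$chl_a),
    pc_med = stats::median(d$pc), car_med = stats::median(d$car)
  )))
rownames(summary_tbl) <- NULL
print(summary_tbl, digits = 3)
utils::write.csv(summary_tbl, "results/01_water_type_summary.csv",
                 row.names = FALSE)

# a small inspectable sample (first 50 records) in the on-disk format
sample_ds <- filter_records(ds, idx = seq_len(min(50, n_records(ds))))
write_dataset_csv(sample_ds, "results/01_dataset_sample.csv")

cat(sprintf(
  "Generated %d records from %d waters (seed %d); Chl-a spans %.2g-%.0f ug/L, PC up to %.0f ug/L.\n",
  n_records(ds), n_waters, seed, min(rrs_meta$chl_a), max(rrs_meta$chl_a),
  max(rrs_meta$pc)
))
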