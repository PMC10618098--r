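#!/usr/bin/env Rscript
# Node-removal control impact for the cohort-mean threat state of each task:
# remove each parcel, re-normalize the dynamics on the reduced network,
# recompute the persistence energy, and report the relative change.

suppressPackageStartupMessages(library(persistenergy))

config <- read_run_config("results/run_config.json")
stage_impact(config)

im <- read_tsv(file.path(config$outdir, "impact.tsv"))
for (tk in unique(im$task)) {
  d <- im[im$task == tk, ]
  top <- head(d[order(-d$value), ], 5)
  cat(sprintf("top control-impact parcels, threat %s (baseline Pe %.4g):\n",
              tk, d$baseline_energy[1]))
  print(top[, c("parcel_label", "value")], row.names = FALSE)
}
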