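#!/usr/bin/env Rscript
# Receptor-map alignment: per-subject absolute control-input difference maps
# (alprazolam vs placebo, threat conditions), mean subject-level Spearman
# correlation with each receptor-like density map, label-permutation p-values
# (500 permutations) and FDR across maps.

suppressPackageStartupMessages(library(persistenergy))

config <- read_run_config("results/run_config.json")
stage_align(config)

al <- read_tsv(file.path(config$outdir, "alignment.tsv"))
cat("alignment of control-input difference maps with receptor maps:\n")
print(al[order(al$task, al$q), c("task", "receptor", "observed_rho", "p", "q")],
      row.names = FALSE, digits = 3)
cat("\n(the first receptor map is rank-blended with the cohort-mean threat\n",
    "activation at Spearman ~0.5 by construction; the rest are independent)\n",
    sep = "")
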