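#!/usr/bin/env Rscript
# Compute the persistence energy of every record's activation state on the
# normalized connectome dynamics (A = W/(lambda_max + c) - I, c = 1, T = 1),
# and per-parcel integrated control input for the threat records.

suppressPackageStartupMessages(library(persistenergy))

config <- read_run_config("results/run_config.json")
stage_energy(config)

en <- read_tsv(file.path(config$outdir, "energy.tsv"))
agg <- aggregate(energy ~ task + condition + drug, en, mean)
cat("mean persistence energy by cell:\n")
print(agg[order(agg$task, agg$condition, agg$drug), ], row.names = FALSE)
tm <- subset(en, task == "memory" & condition == "threat")
r <- tapply(tm$energy, interaction(tm$group, tm$drug), mean)
cat(sprintf("\nthreat-memory mean Pe — relatives drug/placebo ratio: %.3f; controls: %.3f\n",
            r[["relative.alprazolam"]] / r[["relative.placebo"]],
            r[["control.alprazolam"]] / r[["control.placebo"]]))
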