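#!/usr/bin/env Rscript
# Mixed-effects inference: persistence energy ~ drug * group (random
# intercept per subject) per task x condition with FDR across conditions
# within task; efficiency ~ energy + drug + group + age + sex with FDR on
# the energy slope across all six cells; demographics comparison table.

suppressPackageStartupMessages(library(persistenergy))

config <- read_run_config("results/run_config.json")
stage_stats(config)

em <- read_tsv(file.path(config$outdir, "energy_models.tsv"))
key <- subset(em, symbol == "gamma11",
              select = c(task, condition, estimate, se, df, p, q))
cat("group x drug interaction (gamma11) per task x condition:\n")
print(key[order(key$task, key$condition), ], row.names = FALSE, digits = 3)

ef <- read_tsv(file.path(config$outdir, "efficiency_models.tsv"))
bet <- subset(ef, symbol == "beta",
              select = c(task, condition, estimate, p, q))
cat("\nefficiency ~ persistence energy slope (beta) per cell:\n")
print(bet[order(bet$task, bet$condition), ], row.names = FALSE, digits = 3)

cat("\ndemographics comparison:\n")
print(read_tsv(file.path(config$outdir, "demographics_stats.tsv")),
      row.names = FALSE, digits = 3)
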