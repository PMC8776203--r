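#!/usr/bin/env Rscript
# Simulate the study: a 4-time-point (4/8/24/48 h), two-arm (treated vs
# solvent control), 3-replicate bulk RNA-seq count experiment over ~12,000
# expression-filtered genes, with planted trajectory archetypes recording
# which genes respond, when, in which direction and by which mechanism.
library(tctargets)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_genes = 12000, seed = 1)
sim <- generate_counts(cfg)
write_experiment(sim$experiment, sim$truth, out)

cat("Simulated", nrow(sim$experiment$counts), "genes x",
    ncol(sim$experiment$counts), "libraries\n")
print(table(sim$truth$archetype))
cat("Non-null genes:", sum(sim$truth$archetype != "null"),
    "| onset distribution (non-null):\n")
print(table(sim$truth$onset_h[sim$truth$archetype != "null"]))
cat("Wrote counts.tsv, design.tsv, truth.tsv under", out, "\n")
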