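#!/usr/bin/env Rscript
# Generate the desk-scale synthetic screening dataset and write the three
# input tables plus the ground-truth sidecar under results/data/.
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(oncoforest))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating the desk preset (300 cells x 40 drugs x 145 genes), seed ", seed)
model <- desk_preset(seed = seed)
d <- generate_dataset(model)

write_panel(d$panel, file.path(out, "panel.csv"))
write_drugs(d$drugs, file.path(out, "drugs.csv"))
write_sensitivity(d$sens, file.path(out, "sensitivity.csv"))
write_ground_truth(model, file.path(out, "ground_truth.json"))

y <- d$sens$log10_ic50
message(sprintf("wrote %d records; log10 IC50 mean %.2f sd %.2f; active@1uM %.1f%%",
                nrow(d$sens), mean(y), sd(y), 100 * mean(y <= -6)))
message("tables in ", normalizePath(out))
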