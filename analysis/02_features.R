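#!/usr/bin/env Rscript
# Entropy-rank the oncogene panel, assemble the labeled feature matrix at
# the 1 uM cutoff, and write both under results/.
# Usage: Rscript analysis/02_features.R  (expects results/data from 01)

suppressMessages(library(oncoforest))

dat <- file.path("results", "data")
stopifnot(dir.exists(dat))
panel <- read_panel(file.path(dat, "panel.csv"))
drugs <- read_drugs(file.path(dat, "drugs.csv"))
sens <- read_sensitivity(file.path(dat, "sensitivity.csv"))
flt <- filter_dataset(panel, sens)

ent <- mutation_entropy(flt$panel)
ranked <- data.frame(gene_id = select_top_entropy_genes(flt$panel, ncol(flt$panel$mutation)))
ranked$entropy_bits <- ent[ranked$gene_id]
write.csv(ranked, file.path("results", "gene_entropy.csv"), row.names = FALSE)
message(sprintf("entropy range %.3f-%.3f bits across %d genes",
                min(ent), max(ent), length(ent)))

fm <- assemble_matrix(flt$panel, drugs, flt$sens,
                      labeling = labeling_config(1e-6))
print(fm)
write_feature_matrix(fm, file.path("results", "feature_matrix_1um.csv"))
message("feature matrix written to results/feature_matrix_1um.csv")
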