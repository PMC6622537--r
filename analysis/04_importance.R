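#!/usr/bin/env Rscript
# Gini-importance study: global gene ranking, per-drug top genes
# (mean + 2 sd rule), and the minimal-gene-set sweep.
# Usage: Rscript analysis/04_importance.R [seed]

suppressMessages(library(oncoforest))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
dat <- file.path("results", "data")
panel <- read_panel(file.path(dat, "panel.csv"))
drugs <- read_drugs(file.path(dat, "drugs.csv"))
sens <- read_sensitivity(file.path(dat, "sensitivity.csv"))
flt <- filter_dataset(panel, sens)
cfg <- rf_config(n_trees = 500L, seed = seed)

fm <- assemble_matrix(flt$panel, drugs, flt$sens)
ranking <- rank_gene_importance(fm, cfg)
write.csv(ranking, "results/importance_global.csv", row.names = FALSE)
message("top 10 genes by Gini importance: ",
        paste(ranking$feature_id[1:10], collapse = ", "))

truth <- jsonlite::read_json(file.path(dat, "ground_truth.json"),
                             simplifyVector = TRUE)
hits <- sum(truth$causal_genes %in% ranking$feature_id[1:20])
message(sprintf("%d of %d planted causal genes sit in the top 20 ranks",
                hits, length(truth$causal_genes)))

pd <- per_drug_top_genes(flt$panel, drugs, flt$sens, cfg = cfg)
counts <- sort(pd$gene_counts, decreasing = TRUE)
write.csv(data.frame(gene_id = names(counts), n_drugs_top = counts),
          "results/importance_per_drug_counts.csv", row.names = FALSE)
message("gene top-ranking for most drugs: ", names(counts)[1],
        " (", counts[1], " drugs)")

sizes <- sort(unique(c(145L, 100L, 75L, 50L, 30L, 15L, 5L)), decreasing = TRUE)
ms <- minimal_gene_search(flt$panel, drugs, flt$sens, cfg,
                          subset_sizes = sizes, k = 5L, ranking = ranking)
write.csv(ms$metrics, "results/minimal_gene_metrics.csv", row.names = FALSE)
print(ms$metrics)
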