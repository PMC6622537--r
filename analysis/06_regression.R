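#!/usr/bin/env Rscript
# log10 IC50 regression study on the top-50 importance genes: pooled
# 5-fold CV, y-randomization, leave-one-drug-out blind tests, and dummy
# regressor baselines.
# Usage: Rscript analysis/06_regression.R [seed]

suppressMessages(library(oncoforest))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
dat <- file.path("results", "data")
panel <- read_panel(file.path(dat, "panel.csv"))
drugs <- read_drugs(file.path(dat, "drugs.csv"))
sens <- read_sensitivity(file.path(dat, "sensitivity.csv"))
flt <- filter_dataset(panel, sens)
cfg <- rf_config(n_trees = 500L, seed = seed)

# pipeline order: the regression matrix keeps the top-50 genes by global
# Gini importance of the 1 uM classifier
ranking <- rank_gene_importance(
  assemble_matrix(flt$panel, drugs, flt$sens), cfg)
top50 <- ranking$feature_id[1:50]

fm <- assemble_matrix(flt$panel, drugs, flt$sens, gene_subset = top50,
                      mode = "regress")
cv <- regression_cv(fm, cfg, k = 5L)
message(sprintf("pooled 5-fold CV: RMSE %.3f, Pearson %.3f, Spearman %.3f",
                cv$pooled$rmse, cv$pooled$pearson_r, cv$pooled$spearman_rho))
write.csv(cv$per_fold, "results/regression_cv_folds.csv", row.names = FALSE)
write.csv(cv$predictions, "results/regression_predictions.csv", row.names = FALSE)

yr <- regression_cv(fm, cfg, k = 5L, shuffle_train_targets = TRUE)
message(sprintf("y-randomized pooled Pearson %.3f", yr$pooled$pearson_r))

lodo <- leave_one_drug_out(flt$panel, drugs, flt$sens, gene_subset = top50,
                           cfg = cfg)
write.csv(lodo$per_drug, "results/regression_lodo.csv", row.names = FALSE)
message(sprintf("leave-one-drug-out mean: RMSE %.3f, Pearson %.3f",
                lodo$mean[["rmse"]], lodo$mean[["pearson_r"]]))

base <- do.call(rbind, lapply(c("zero_rule_mean", "quantile", "knn9"),
  function(s) {
    b <- dummy_regressor(fm, s, q = 0.5, k_folds = 10L, seed = seed)
    data.frame(strategy = s, rmse = b$pooled$rmse)
  }))
write.csv(base, "results/regression_baselines.csv", row.names = FALSE)
print(base)
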