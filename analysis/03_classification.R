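#!/usr/bin/env Rscript
# Classification study on the simulated screen: 5-fold CV at the
# 0.1/1/10 uM cutoffs, y-randomization control, dummy baselines,
# leave-drugs-out blind validation, and a reduced cutoff-sweep ROC.
# Runtime: roughly half an hour single-threaded at 500 trees.
# Usage: Rscript analysis/03_classification.R [seed]

suppressMessages(library(oncoforest))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
dat <- file.path("results", "data")
panel <- read_panel(file.path(dat, "panel.csv"))
drugs <- read_drugs(file.path(dat, "drugs.csv"))
sens <- read_sensitivity(file.path(dat, "sensitivity.csv"))
flt <- filter_dataset(panel, sens)
cfg <- rf_config(n_trees = 500L, seed = seed)

rows <- list(); yr_rows <- list(); base_rows <- list()
for (um in c(0.1, 1, 10)) {
  fm <- assemble_matrix(flt$panel, drugs, flt$sens,
                        labeling = labeling_config(um * 1e-6))
  cv <- kfold_cv(fm, cfg, k = 5L)
  message(sprintf("cutoff %4.1f uM: accuracy %.2f +/- %.2f, kappa %.2f",
                  um, cv$mean[["accuracy"]], cv$sd[["accuracy"]],
                  cv$mean[["kappa"]]))
  rows[[length(rows) + 1L]] <- data.frame(cutoff_um = um, t(cv$mean))

  yr <- kfold_cv(fm, cfg, k = 5L, shuffle_train_labels = TRUE)
  message(sprintf("  y-randomized kappa %.3f", yr$mean[["kappa"]]))
  yr_rows[[length(yr_rows) + 1L]] <- data.frame(cutoff_um = um, t(yr$mean))

  for (s in c("zero_rule", "stratified", "uniform", "knn9")) {
    b <- dummy_classifier(fm, s, k_folds = 10L, seed = seed)
    base_rows[[length(base_rows) + 1L]] <-
      data.frame(cutoff_um = um, strategy = s,
                 accuracy = b$pooled$accuracy, npv = b$pooled$npv,
                 kappa = b$pooled$kappa)
  }
}
write.csv(do.call(rbind, rows), "results/classification_cv.csv", row.names = FALSE)
write.csv(do.call(rbind, yr_rows), "results/classification_yrand.csv", row.names = FALSE)
write.csv(do.call(rbind, base_rows), "results/classification_baselines.csv", row.names = FALSE)

lodo <- leave_drugs_out_cv(flt$panel, drugs, flt$sens, cfg = cfg,
                           n_out = 4L, rounds = 10L)
message(sprintf("leave-drugs-out: accuracy %.2f +/- %.2f, kappa %.2f",
                lodo$mean[["accuracy"]], lodo$sd[["accuracy"]],
                lodo$mean[["kappa"]]))
write.csv(lodo$per_fold, "results/classification_lodo.csv", row.names = FALSE)

sweep_um <- c(0.05, 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000, 3000)
roc <- suppressWarnings(cutoff_sweep(flt$panel, drugs, flt$sens, cfg = cfg,
                                     cutoffs_um = sweep_um, k = 5L))
message(sprintf("cutoff-sweep AUC over %d usable cutoffs: %.3f",
                nrow(roc$points), roc$auc))
write.csv(roc$points, "results/roc_points.csv", row.names = FALSE)
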