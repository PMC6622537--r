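cfg_fast <- function(seed = 3L, trees = 60L) rf_config(n_trees = trees, seed = seed)

test_that("classifier separates a noiseless single-gene rule and is deterministic", {
  set.seed(2)
  n <- 60L
  feats <- cbind(matrix(rbinom(n * 5, 1, 0.5), n, 5),
                 matrix(rnorm(n * 10), n, 10))
  colnames(feats) <- c(sprintf("g%d", 1:5), sprintf("fp_%04d", 1:10))
  fm <- structure(list(
    drug_id = rep("d", n), cell_line_id = sprintf("c%d", 1:n),
    features = feats, gene_ids = sprintf("g%d", 1:5), mode = "classify",
    label = factor(ifelse(feats[, "g3"] == 1, "active", "inactive"),
                   levels = c("active", "inactive")),
    cutoff_molar = 1e-6), class = "feature_matrix")
  model <- train_classifier(fm, cfg_fast())
  expect_equal(mean(predict(model, fm) == fm$label), 1.0)
  # the predictive gene dominates the importance ranking
  expect_identical(names(which.max(model$importance[fm$gene_ids])), "g3")
  # identical seed, identical predictions
  model2 <- train_classifier(fm, cfg_fast())
  expect_identical(predict(model2, fm), predict(model, fm))
  # single-class training data is refused
  fm_bad <- fm; fm_bad$label <- factor(rep("active", n),
                                       levels = c("active", "inactive"))
  expect_error(train_classifier(fm_bad, cfg_fast()),
               class = "oncoforest_degenerate_error")
})

test_that("k-fold partition covers every row exactly once", {
  d <- small_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  res <- kfold_cv(fm, cfg_fast(), k = 5L)
  expect_identical(res$pooled$N, nrow(fm$features))
  expect_identical(nrow(res$per_fold), 5L)
  # a leaked label column is learned nearly perfectly
  leak <- fm
  leak$features <- cbind(leak$features,
                         leaky = as.numeric(leak$label == "active"))
  res_leak <- kfold_cv(leak, rf_config(n_trees = 60L, m_try = 300L, seed = 3L),
                       k = 3L)
  expect_gte(res_leak$mean[["accuracy"]], 0.99)
})

test_that("cross-validation schemes agree on the same data", {
  d <- mid_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  cvk <- kfold_cv(fm, rf_config(n_trees = 100L, seed = 5L), k = 5L)
  # 50% holdout comparison
  cv2 <- kfold_cv(fm, rf_config(n_trees = 100L, seed = 6L), k = 2L)
  expect_lt(abs(cvk$mean[["kappa"]] - cv2$mean[["kappa"]]), 0.08)
})

test_that("y-randomization collapses kappa to chance, identity shuffle does not", {
  d <- mid_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  yr <- y_randomize(fm, rf_config(n_trees = 80L, seed = 9L), k = 3L,
                    repeats = 2L)
  expect_lt(abs(yr$mean_kappa), 0.05)
  expect_identical(nrow(yr$per_repeat), 2L)
  # distinct repeats use distinct shuffles
  expect_false(identical(yr$repeats[[1]]$per_fold$kappa,
                         yr$repeats[[2]]$per_fold$kappa))
})

test_that("leave-drugs-out keeps train and test drug sets disjoint", {
  d <- mid_dataset()
  res <- leave_drugs_out_cv(d$panel, d$drugs, d$sens,
                            cfg = rf_config(n_trees = 80L, seed = 4L),
                            n_out = 5L, rounds = 3L)
  expect_identical(nrow(res$per_fold), 3L)
  for (r in 1:3) expect_length(res$held_out_drugs[[r]], 5L)
  # generalization still above chance on planted-signal data (blind
  # drugs lose the memorisable potency offsets, so the margin is modest)
  expect_gt(res$mean[["kappa"]], 0.05)
  expect_error(
    leave_drugs_out_cv(d$panel, d$drugs, d$sens, n_out = 0L),
    class = "oncoforest_config_error")
})

test_that("dummy baselines have their forced statistics", {
  set.seed(77)
  n <- 2000L
  feats <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("g1", "fp_0001", "fp_0002")))
  lab <- factor(rep(c("active", "inactive"), c(600, 1400)),
                levels = c("active", "inactive"))
  fm <- structure(list(drug_id = rep("d", n), cell_line_id = sprintf("c%d", 1:n),
                       features = feats, gene_ids = "g1", mode = "classify",
                       label = lab, cutoff_molar = 1e-6),
                  class = "feature_matrix")
  zr <- dummy_classifier(fm, "zero_rule", k_folds = 10L, seed = 1L)
  # majority (inactive) assigned everywhere: accuracy = majority fraction
  expect_equal(zr$pooled$accuracy, 0.70)
  expect_equal(zr$pooled$sensitivity, 0)
  un <- dummy_classifier(fm, "uniform", k_folds = 10L, seed = 1L)
  expect_lt(abs(un$pooled$accuracy - 0.5), 0.05)
  expect_error(dummy_classifier(fm, "nonsense"), "arg")
})

test_that("knn9 dummy tracks a strong nearest-neighbour structure", {
  d <- small_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  kn <- dummy_classifier(fm, "knn9", k_folds = 5L, seed = 2L)
  st <- dummy_classifier(fm, "stratified", k_folds = 5L, seed = 2L)
  # feature-based baseline clearly beats the label-only baseline here
  expect_gt(kn$pooled$kappa, st$pooled$kappa + 0.2)
})

test_that("the cutoff-sweep ROC is anchored and skips impossible cutoffs", {
  d <- small_dataset()
  roc <- suppressWarnings(cutoff_sweep(
    d$panel, d$drugs, d$sens, cfg = rf_config(n_trees = 50L, seed = 2L),
    cutoffs_um = c(1e-6, 0.5, 1, 5, 1e6), k = 3L))
  # extreme cutoffs produce single-class labelings and are dropped
  expect_lt(nrow(roc$points), 5L)
  expect_true(all(roc$points$fpr >= 0 & roc$points$fpr <= 1))
  expect_true(roc$auc >= 0 && roc$auc <= 1)
})
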