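test_that("a perfectly predictive gene ranks first", {
  set.seed(5)
  n <- 80L
  feats <- cbind(matrix(rbinom(n * 6, 1, 0.5), n, 6),
                 matrix(rnorm(n * 20), n, 20))
  colnames(feats) <- c(sprintf("gene_%02d", 1:6), sprintf("fp_%04d", 1:20))
  fm <- structure(list(drug_id = rep("d", n), cell_line_id = sprintf("c%d", 1:n),
                       features = feats, gene_ids = sprintf("gene_%02d", 1:6),
                       mode = "classify",
                       label = factor(ifelse(feats[, "gene_04"] == 1,
                                             "active", "inactive"),
                                      levels = c("active", "inactive")),
                       cutoff_molar = 1e-6),
                  class = "feature_matrix")
  tab <- rank_gene_importance(fm, rf_config(n_trees = 100L, seed = 2L))
  expect_identical(tab$feature_id[1], "gene_04")
  expect_identical(tab$rank, 1:6)
  expect_true(all(diff(tab$gini_importance) <= 0))
  expect_true(all(tab$gini_importance >= 0))
})

test_that("pure-noise labels produce no dominant gene", {
  set.seed(6)
  n <- 400L
  feats <- matrix(rbinom(n * 30, 1, 0.5), n, 30,
                  dimnames = list(NULL, sprintf("gene_%02d", 1:30)))
  ratios <- vapply(1:5, function(s) {
    set.seed(100 + s)
    fm <- structure(list(drug_id = rep("d", n),
                         cell_line_id = sprintf("c%d", 1:n),
                         features = feats, gene_ids = colnames(feats),
                         mode = "classify",
                         label = factor(sample(c("active", "inactive"), n, TRUE),
                                        levels = c("active", "inactive")),
                         cutoff_molar = 1e-6),
                    class = "feature_matrix")
    tab <- rank_gene_importance(fm, rf_config(n_trees = 100L, seed = s))
    max(tab$gini_importance) / max(min(tab$gini_importance), 1e-9)
  }, numeric(1))
  expect_lt(mean(ratios), 5)
})

test_that("planted causal genes are recovered by the global ranking", {
  d <- mid_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  tab <- rank_gene_importance(fm, rf_config(n_trees = 150L, seed = 11L))
  hits <- sum(d$model$causal_genes %in% tab$feature_id[1:20])
  expect_gte(hits, 8L)
})

test_that("per-drug top genes follow the mean + 2 sd rule", {
  d <- small_dataset()
  res <- suppressWarnings(per_drug_top_genes(
    d$panel, d$drugs, d$sens, cfg = rf_config(n_trees = 60L, seed = 4L)))
  expect_true(all(names(res$gene_counts) == colnames(d$panel$mutation)))
  some_drug <- names(res$per_drug)[1]
  expect_true(all(res$per_drug[[some_drug]] %in% colnames(d$panel$mutation)))
  # counts are consistent with the per-drug sets
  manual <- table(factor(unlist(res$per_drug),
                         levels = colnames(d$panel$mutation)))
  expect_identical(unname(res$gene_counts), as.integer(manual))
})

test_that("per-drug calls concentrate on the drugs carrying the causal chemistry", {
  d <- mid_dataset()
  m <- d$model
  res <- suppressWarnings(per_drug_top_genes(
    d$panel, d$drugs, d$sens, cfg = rf_config(n_trees = 100L, seed = 8L)))
  # for each causal gene, the drugs calling it top should be enriched in
  # drugs that actually carry at least one of its interaction bits
  eff <- m$interaction_effects
  bits <- d$drugs$fingerprints[, 192L + eff$bit[eff$gene %in% m$causal_genes],
                               drop = FALSE]
  called <- lapply(m$causal_genes, function(g) {
    names(Filter(function(v) g %in% v, res$per_drug))
  })
  n_called <- sum(lengths(called))
  expect_gte(n_called, 5L)  # planted structure must generate calls at all
  hit <- 0L
  for (i in seq_along(m$causal_genes)) {
    g_bits <- eff$bit[eff$gene == m$causal_genes[i]]
    carriers <- d$drugs$drug_ids[
      rowSums(d$drugs$fingerprints[, 192L + g_bits, drop = FALSE]) > 0]
    hit <- hit + sum(called[[i]] %in% carriers)
  }
  expect_gte(hit / n_called, 0.70)
})

test_that("all-equal importances yield an empty top set", {
  # direct check of the threshold rule on a constant vector: nothing can
  # exceed mean + 2 sd when sd = 0
  imp <- rep(3.3, 145)
  expect_length(imp[imp > mean(imp) + 2 * sqrt(mean((imp - mean(imp))^2))], 0L)
})

test_that("minimal gene search tracks subset size and reuses the ranking", {
  d <- small_dataset()
  cfg <- rf_config(n_trees = 60L, seed = 12L)
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  ranking <- rank_gene_importance(fm, cfg)
  res <- minimal_gene_search(d$panel, d$drugs, d$sens, cfg,
                             subset_sizes = c(30L, 10L, 0L), k = 3L,
                             ranking = ranking)
  expect_identical(sort(res$metrics$size), c(0L, 10L, 30L))
  # N = all genes equals a direct kfold run on the same column order
  full <- kfold_cv(assemble_matrix(d$panel, d$drugs, d$sens,
                                   gene_subset = ranking$feature_id),
                   cfg, k = 3L)
  expect_equal(res$metrics$kappa[res$metrics$size == 30L],
               full$mean[["kappa"]])
  # chemistry-only ablation runs and underperforms the full panel
  expect_lt(res$metrics$kappa[res$metrics$size == 0L],
            res$metrics$kappa[res$metrics$size == 30L])
  expect_error(minimal_gene_search(d$panel, d$drugs, d$sens, cfg,
                                   subset_sizes = integer(0)),
               class = "oncoforest_config_error")
  expect_error(minimal_gene_search(d$panel, d$drugs, d$sens, cfg,
                                   subset_sizes = 31L),
               class = "oncoforest_config_error")
})
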