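test_that("masking is exact, seeded, and reversible via the truth store", {
  d <- small_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  n <- nrow(fm$features)
  mk <- mask_values(fm, mask_plan(0.10, seed = 4L))
  expect_length(mk$masked_rows, round(0.10 * n))
  expect_true(all(is.na(mk$masked$label[mk$masked_rows])))
  expect_identical(mk$masked$label[-mk$masked_rows], fm$label[-mk$masked_rows])
  expect_identical(mk$truth, fm$label)
  # deterministic per seed
  mk2 <- mask_values(fm, mask_plan(0.10, seed = 4L))
  expect_identical(mk2$masked_rows, mk$masked_rows)
  # two seeds overlap like independent draws (~ f^2 of rows)
  mk3 <- mask_values(fm, mask_plan(0.10, seed = 5L))
  overlap <- length(intersect(mk$masked_rows, mk3$masked_rows)) / n
  expect_lt(abs(overlap - 0.01), 0.012)
  expect_error(mask_plan(0), class = "oncoforest_config_error")
  expect_error(mask_plan(1), class = "oncoforest_config_error")
})

test_that("identical-feature rows are imputed by their neighbours' label", {
  set.seed(9)
  # two well-separated clusters so each masked row's 9-NN neighbourhood
  # is entirely its own cluster; masked rows duplicate observed actives
  base <- rbind(matrix(rnorm(15 * 8, mean = 10), 15, 8),
                matrix(rnorm(15 * 8, mean = 0), 15, 8))
  colnames(base) <- sprintf("fp_%04d", 1:8)
  feats <- rbind(base, base[1:5, ])
  lab <- factor(c(rep("active", 15), rep("inactive", 15), rep("active", 5)),
                levels = c("active", "inactive"))
  fm <- structure(list(drug_id = rep("d", 35), cell_line_id = sprintf("c%d", 1:35),
                       features = feats, gene_ids = character(0),
                       mode = "classify", label = lab, cutoff_molar = 1e-6),
                  class = "feature_matrix")
  masked <- fm; masked$label[31:35] <- NA
  out <- impute(masked, "knn9")
  expect_identical(as.character(out$label[31:35]), rep("active", 5))
  expect_identical(out$label[1:30], fm$label[1:30])
})

test_that("every method recovers a noiseless single-bit rule", {
  set.seed(10)
  n <- 300L
  g <- rbinom(n, 1, 0.5)
  # the label-determining bit dominates the geometry (noise sd 0.05) so
  # distance-based imputers see label-pure neighbourhoods too
  feats <- cbind(gene_01 = g, matrix(rnorm(n * 5, sd = 0.05), n, 5,
                                     dimnames = list(NULL, sprintf("fp_%04d", 1:5))))
  lab <- factor(ifelse(g == 1, "active", "inactive"),
                levels = c("active", "inactive"))
  fm <- structure(list(drug_id = rep("d", n), cell_line_id = sprintf("c%d", 1:n),
                       features = feats, gene_ids = "gene_01",
                       mode = "classify", label = lab, cutoff_molar = 1e-6),
                  class = "feature_matrix")
  mk <- mask_values(fm, mask_plan(0.2, seed = 2L))
  for (method in c("rf_iterative", "knn9", "lasso_logistic", "cart")) {
    out <- impute(mk$masked, method, cfg = rf_config(n_trees = 50L, seed = 3L))
    acc <- mean(out$label[mk$masked_rows] == mk$truth[mk$masked_rows])
    expect_equal(acc, 1.0, info = method)
    expect_identical(out$label[-mk$masked_rows], fm$label[-mk$masked_rows])
  }
})

test_that("imputation on planted-signal data beats the majority rate", {
  d <- mid_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  mk <- mask_values(fm, mask_plan(0.10, seed = 6L))
  majority_rate <- max(prop.table(table(mk$truth[mk$masked_rows])))
  for (method in c("knn9", "lasso_logistic")) {
    out <- impute(mk$masked, method, cfg = rf_config(n_trees = 60L, seed = 3L))
    acc <- mean(out$label[mk$masked_rows] == mk$truth[mk$masked_rows])
    expect_gte(acc, 0.75)
    expect_gt(acc, majority_rate)
  }
})

test_that("degenerate masking inputs are handled", {
  d <- small_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  all_masked <- fm; all_masked$label[] <- NA
  expect_error(impute(all_masked, "knn9"), class = "oncoforest_empty_error")
  one_class <- fm
  one_class$label[one_class$label == "inactive" & !is.na(one_class$label)] <- "active"
  one_class$label[1:10] <- NA
  expect_warning(out <- impute(one_class, "cart"), "single-class")
  expect_true(all(out$label[1:10] == "active"))
})

test_that("the masking experiment reports a full fraction-by-method grid", {
  d <- small_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  rep_ <- imputation_experiment(fm, fractions = c(0.1, 0.3),
                                methods = c("knn9", "cart"),
                                cfg = rf_config(n_trees = 40L, seed = 7L),
                                k = 3L)
  expect_identical(nrow(rep_), 4L)
  expect_setequal(rep_$method, c("knn9", "cart"))
  expect_true(all(rep_$imputation_accuracy >= 0 & rep_$imputation_accuracy <= 1))
  expect_true(all(rep_$n_eval > 0))
})
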