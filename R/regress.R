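#' k-fold cross-validation of the log10 IC50 regressor
#'
#' Every row is predicted exactly once by a forest not trained on it;
#' the headline metrics are pooled over the concatenated out-of-fold
#' predictions, with per-fold metrics supplying dispersion.
#'
#' @param fm regress-mode feature matrix.
#' @param cfg an [rf_config()].
#' @param k folds (default 5).
#' @param shuffle_train_targets permute each training split's targets
#'   before fitting (regression y-randomization); test targets
#'   untouched.
#' @return list with `pooled` (a `reg_metrics`), `per_fold` data.frame
#'   (fold, rmse, pearson_r, spearman_rho), and `predictions`
#'   (data.frame: drug_id, cell_line_id, observed, predicted, fold).
#' @export
regression_cv <- function(fm, cfg = rf_config(), k = 5L,
                          shuffle_train_targets = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"), fm$mode == "regress")
  n <- nrow(fm$features)
  folds <- make_folds(n, k, cfg$seed)
  pred <- numeric(n)
  fold_of <- integer(n)
  per <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train <- fm_subset(fm, setdiff(seq_len(n), test_idx))
    if (shuffle_train_targets) {
      set.seed(derive_seed(cfg$seed, "yrand_reg", i))
      train$target <- sample(train$target)
    }
    f_cfg <- cfg; f_cfg$seed <- derive_seed(cfg$seed, "reg_fit", i)
    model <- train_regressor(train, f_cfg)
    pred[test_idx] <- predict(model, fm$features[test_idx, , drop = FALSE])
    fold_of[test_idx] <- i
    m <- regression_metrics(pred[test_idx], fm$target[test_idx])
    per[[i]] <- data.frame(fold = i, rmse = m$rmse, pearson_r = m$pearson_r,
                           spearman_rho = m$spearman_rho)
  }
  list(pooled = regression_metrics(pred, fm$target),
       per_fold = do.call(rbind, per),
       predictions = data.frame(drug_id = fm$drug_id,
                                cell_line_id = fm$cell_line_id,
                                observed = fm$target, predicted = pred,
                                fold = fold_of, stringsAsFactors = FALSE))
}

#' Leave-one-drug-out validation of the regressor
#'
#' For each held-out drug, a regressor trained on all other drugs
#' predicts the held-out drug's log10 IC50 values — the blind-test
#' scenario for a compound never screened before.
#'
#' @param panel,drugs,sens filtered input tables.
#' @param gene_subset genes to use (conventionally the top-50
#'   importance list).
#' @param cfg an [rf_config()].
#' @param drug_ids drugs to hold out; default: 9 drawn at random.
#' @param min_records skip (with error) drugs with fewer records.
#' @return list with `per_drug` data.frame (drug_id, rmse, pearson_r,
#'   spearman_rho, n) and `mean` (named vector of column means).
#' @export
leave_one_drug_out <- function(panel, drugs, sens, gene_subset = NULL,
                               cfg = rf_config(), drug_ids = NULL,
                               min_records = 10L) {
  fm <- assemble_matrix(panel, drugs, sens, gene_subset, mode = "regress")
  if (is.null(drug_ids)) {
    set.seed(derive_seed(cfg$seed, "lodo_reg_pick"))
    drug_ids <- sample(drugs$drug_ids, min(9L, length(drugs$drug_ids) - 1L))
  }
  n <- nrow(fm$features)
  rows <- lapply(drug_ids, function(d) {
    test_idx <- which(fm$drug_id == d)
    if (length(test_idx) < min_records) {
      of_error(sprintf("drug %s has only %d records", d, length(test_idx)),
               "oncoforest_config_error")
    }
    train <- fm_subset(fm, setdiff(seq_len(n), test_idx))
    d_cfg <- cfg; d_cfg$seed <- derive_seed(cfg$seed, "lodo_reg", d)
    model <- train_regressor(train, d_cfg)
    p <- predict(model, fm$features[test_idx, , drop = FALSE])
    m <- regression_metrics(p, fm$target[test_idx])
    data.frame(drug_id = d, rmse = m$rmse, pearson_r = m$pearson_r,
               spearman_rho = m$spearman_rho, n = m$n,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_drug = per,
       mean = colMeans(per[, c("rmse", "pearson_r", "spearman_rho")],
                       na.rm = TRUE))
}
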