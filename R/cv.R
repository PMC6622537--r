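# internal: fold assignment. Rows are shuffled with a derived seed
# before contiguous splitting; ordered_folds = TRUE reproduces the
# literal "first 80% of the rows" contiguous scheme instead.
make_folds <- function(n, k, seed, ordered_folds = FALSE) {
  if (k < 2L || k > n) of_error(sprintf("k must lie in [2, %d]", n),
                                "oncoforest_config_error")
  idx <- if (ordered_folds) seq_len(n) else {
    set.seed(derive_seed(seed, "folds"))
    sample.int(n)
  }
  split(idx, cut(seq_len(n), k, labels = FALSE))
}

#' k-fold cross-validation of the activity classifier
#'
#' Splits the rows into `k` disjoint test folds (shuffled with a
#' recorded seed, or contiguous when `ordered_folds = TRUE`), trains a
#' forest on each complement and evaluates the confusion metrics on the
#' held-out fold.  When the training split's minority class falls below
#' `minority_threshold`, SMOTE balancing is applied to the training
#' split only (never to the test fold), unless `smote_before_split =
#' TRUE`, which balances the whole matrix once before splitting.
#'
#' @param fm classify-mode feature matrix.
#' @param cfg an [rf_config()].
#' @param k number of folds (default 5).
#' @param ordered_folds use contiguous unshuffled folds.
#' @param smote use SMOTE balancing on imbalanced training splits.
#' @param smote_before_split balance once before splitting (leakage-prone
#'   but reproduces the historical protocol).
#' @param minority_threshold SMOTE trigger (default 0.20).
#' @param shuffle_train_labels permute each training split's labels
#'   before fitting (the y-randomization null); test labels untouched.
#' @return list with `per_fold` (data.frame of fold metrics), `mean`,
#'   `sd` (named vectors over accuracy/sensitivity/specificity/fpr/npv/
#'   kappa), and `pooled` (a `class_metrics` over all out-of-fold
#'   predictions).
#' @export
kfold_cv <- function(fm, cfg = rf_config(), k = 5L, ordered_folds = FALSE,
                     smote = TRUE, smote_before_split = FALSE,
                     minority_threshold = 0.20,
                     shuffle_train_labels = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"), fm$mode == "classify")
  if (smote_before_split && smote) {
    fm <- smote_balance(fm, minority_threshold,
                        seed = derive_seed(cfg$seed, "smote_pre"))
  }
  n <- nrow(fm$features)
  folds <- make_folds(n, k, cfg$seed, ordered_folds)
  pooled_pred <- character(0); pooled_truth <- character(0)
  metrics <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train <- fm_subset(fm, setdiff(seq_len(n), test_idx))
    test <- fm_subset(fm, test_idx)
    if (shuffle_train_labels) {
      set.seed(derive_seed(cfg$seed, "yrand", i))
      train$label <- sample(train$label)
    }
    if (smote && !smote_before_split) {
      train <- smote_balance(train, minority_threshold,
                             seed = derive_seed(cfg$seed, "smote", i))
    }
    if (nlevels(droplevels(train$label)) < 2L) {
      of_error(sprintf("fold %d training split contains a single class", i),
               "oncoforest_degenerate_error")
    }
    fold_cfg <- cfg; fold_cfg$seed <- derive_seed(cfg$seed, "fit", i)
    model <- train_classifier(train, fold_cfg, importance = FALSE)
    pred <- predict(model, test)
    metrics[[i]] <- compute_metrics(pred, test$label)
    pooled_pred <- c(pooled_pred, as.character(pred))
    pooled_truth <- c(pooled_truth, as.character(test$label))
  }
  out <- summarise_class_metrics(metrics)
  out$pooled <- compute_metrics(pooled_pred, pooled_truth)
  out$k <- k
  out
}

#' y-randomization control for the activity classifier
#'
#' Repeats [kfold_cv()] with the class labels of each training split
#' randomly permuted before fitting; test folds keep their true labels.
#' A sound model collapses to chance (kappa near 0) under this null.
#'
#' @param fm classify-mode feature matrix.
#' @param cfg an [rf_config()].
#' @param k folds per repeat.
#' @param repeats number of independent shuffling repeats (default 5).
#' @param ... passed to [kfold_cv()].
#' @return list with `per_repeat` (data.frame: repeat, mean metrics),
#'   `mean_kappa`, and `repeats` (the full kfold_cv results).
#' @export
y_randomize <- function(fm, cfg = rf_config(), k = 5L, repeats = 5L, ...) {
  runs <- lapply(seq_len(repeats), function(r) {
    r_cfg <- cfg; r_cfg$seed <- derive_seed(cfg$seed, "yrand_repeat", r)
    kfold_cv(fm, r_cfg, k = k, shuffle_train_labels = TRUE, ...)
  })
  per <- do.call(rbind, lapply(seq_len(repeats), function(r) {
    data.frame(repeat_id = r, t(runs[[r]]$mean))
  }))
  list(per_repeat = per, mean_kappa = mean(per$kappa, na.rm = TRUE),
       repeats = runs)
}

#' Leave-drugs-out (blind) cross-validation of the classifier
#'
#' Per round, `n_out` randomly chosen drugs are withheld entirely: every
#' record of a withheld drug is test-only and the training set never
#' contains any test drug.  Simulates prediction for compounds never
#' seen in training.
#'
#' @param panel,drugs,sens filtered input tables.
#' @param gene_subset genes to use (default: all panel genes).
#' @param cfg an [rf_config()].
#' @param labeling a [labeling_config()].
#' @param n_out drugs withheld per round (default 10).
#' @param rounds number of rounds (default 20).
#' @param smote balance imbalanced training sets.
#' @return list with `per_round` metrics data.frame, `mean`, `sd`.
#'   A round whose withheld records contain one class only reports the
#'   undefined ratios as NA with a warning.
#' @export
leave_drugs_out_cv <- function(panel, drugs, sens, gene_subset = NULL,
                               cfg = rf_config(), labeling = labeling_config(),
                               n_out = 10L, rounds = 20L, smote = TRUE) {
  n_drugs <- length(drugs$drug_ids)
  if (n_out < 1L || n_out >= n_drugs) {
    of_error("n_out must lie in [1, number of drugs - 1]",
             "oncoforest_config_error")
  }
  fm <- assemble_matrix(panel, drugs, sens, gene_subset, labeling, "classify")
  metrics <- vector("list", rounds)
  held <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    set.seed(derive_seed(cfg$seed, "lodo", r))
    out_drugs <- sample(drugs$drug_ids, n_out)
    held[[r]] <- out_drugs
    test_rows <- which(fm$drug_id %in% out_drugs)
    train <- fm_subset(fm, setdiff(seq_len(nrow(fm$features)), test_rows))
    test <- fm_subset(fm, test_rows)
    stopifnot(length(intersect(unique(train$drug_id), unique(test$drug_id))) == 0L)
    if (smote) {
      train <- smote_balance(train, seed = derive_seed(cfg$seed, "lodo_smote", r))
    }
    r_cfg <- cfg; r_cfg$seed <- derive_seed(cfg$seed, "lodo_fit", r)
    model <- train_classifier(train, r_cfg, importance = FALSE)
    if (nlevels(droplevels(test$label)) < 2L) {
      warning(sprintf("round %d: withheld drugs contain a single class; some metrics NA", r),
              call. = FALSE)
    }
    metrics[[r]] <- compute_metrics(predict(model, test), test$label)
  }
  out <- summarise_class_metrics(metrics, id_col = "round")
  out$held_out_drugs <- held
  out
}

#' Activity-cutoff sweep and ROC curve
#'
#' Re-labels the records at each IC50 cutoff, balances with SMOTE when
#' the minority class falls below 20%, runs [kfold_cv()], and records
#' the cross-validated mean (FPR, sensitivity) point.  The ROC curve is
#' traced by the cutoffs (not by a score threshold); its AUC is the
#' trapezoid area over the FPR-sorted points augmented with the (0,0)
#' and (1,1) anchors.  A cutoff whose labeling is single-class even
#' after balancing is skipped with a warning.
#'
#' @param panel,drugs,sens filtered input tables.
#' @param gene_subset genes to use (default: all).
#' @param cfg an [rf_config()].
#' @param cutoffs_um cutoffs in micromolar (default
#'   [default_cutoff_grid_um()]).
#' @param k folds.
#' @param shuffle_train_labels run the sweep under the y-randomization
#'   null instead.
#' @return an `roc_curve`: list with `points` (data.frame cutoff_um,
#'   fpr, tpr) and `auc`.
#' @export
cutoff_sweep <- function(panel, drugs, sens, gene_subset = NULL,
                         cfg = rf_config(), cutoffs_um = default_cutoff_grid_um(),
                         k = 5L, shuffle_train_labels = FALSE) {
  if (any(cutoffs_um <= 0)) of_error("cutoffs must be strictly positive",
                                     "oncoforest_config_error")
  pts <- lapply(cutoffs_um, function(um) {
    lab <- labeling_config(um * 1e-6)
    fm <- assemble_matrix(panel, drugs, sens, gene_subset, lab, "classify")
    if (min(table(fm$label)) < 2L * k) {
      warning(sprintf("cutoff %g uM: too few records in one class; point skipped", um),
              call. = FALSE)
      return(NULL)
    }
    cut_cfg <- cfg; cut_cfg$seed <- derive_seed(cfg$seed, "sweep", um)
    res <- tryCatch(
      kfold_cv(fm, cut_cfg, k = k, shuffle_train_labels = shuffle_train_labels),
      oncoforest_degenerate_error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("cutoff %g uM: single-class training fold; point skipped", um),
              call. = FALSE)
      return(NULL)
    }
    data.frame(cutoff_um = um, fpr = res$mean[["fpr"]],
               tpr = res$mean[["sensitivity"]])
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0L) {
    of_error("no cutoff produced a usable ROC point", "oncoforest_empty_error")
  }
  structure(list(points = pts, auc = trapezoid_auc(pts$fpr, pts$tpr)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d cutoff points, AUC = %.3f\n",
              nrow(x$points), x$auc))
  invisible(x)
}
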