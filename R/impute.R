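#' Masking plan for simulated missing activity values
#'
#' @param fraction fraction of records to mask, strictly inside (0, 1);
#'   the screening benchmark uses 0.10/0.20/0.30/0.40.
#' @param seed integer seed; masked rows are drawn uniformly without
#'   replacement.
#' @return a `mask_plan` object.
#' @export
mask_plan <- function(fraction, seed = 1L) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    of_error("mask fraction must lie strictly inside (0, 1)",
             "oncoforest_config_error")
  }
  structure(list(fraction = fraction, seed = as.integer(seed)),
            class = "mask_plan")
}

#' Mask activity labels
#'
#' Removes the class label of `round(fraction * n)` uniformly chosen
#' rows, keeping the originals in a truth store for scoring.
#'
#' @param fm classify-mode feature matrix with true labels.
#' @param plan a [mask_plan()].
#' @return list with `masked` (feature matrix whose `label` has NA at
#'   the masked rows), `truth` (factor of the original labels) and
#'   `masked_rows` (integer indices).
#' @export
mask_values <- function(fm, plan) {
  stopifnot(inherits(fm, "feature_matrix"), fm$mode == "classify",
            inherits(plan, "mask_plan"))
  n <- nrow(fm$features)
  n_mask <- round(plan$fraction * n)
  set.seed(derive_seed(plan$seed, "mask"))
  masked_rows <- sort(sample.int(n, n_mask))
  out <- fm
  out$label[masked_rows] <- NA
  list(masked = out, truth = fm$label, masked_rows = masked_rows)
}

#' Impute masked activity labels
#'
#' Fills the missing class labels of a masked feature matrix from the
#' observed rows, using all feature columns as predictors:
#' \describe{
#'   \item{rf_iterative}{iterative random-forest imputation
#'     (missForest-style): fit a forest on label-observed rows, predict
#'     the masked labels, refit including the imputations, and repeat
#'     until the imputed labels stabilise (at most `max_iter`
#'     iterations; 500 trees by default).}
#'   \item{knn9}{majority label of the 9 nearest observed rows
#'     (Euclidean).}
#'   \item{lasso_logistic}{L1-penalised logistic regression on the
#'     observed rows; the penalty is chosen by internal cross-validation
#'     over a 100-step lambda path.}
#'   \item{cart}{a classification tree (recursive partitioning) fit on
#'     the observed rows.}
#' }
#' Observed labels are never modified.
#'
#' @param masked the `masked` element of [mask_values()].
#' @param method one of `"rf_iterative"`, `"knn9"`, `"lasso_logistic"`,
#'   `"cart"`.
#' @param cfg an [rf_config()] (used by `rf_iterative`).
#' @param max_iter iteration cap for `rf_iterative` (default 10).
#' @param seed seed for stochastic imputers.
#' @return the completed feature matrix (no NA labels).
#' @export
impute <- function(masked, method = c("rf_iterative", "knn9",
                                      "lasso_logistic", "cart"),
                   cfg = rf_config(), max_iter = 10L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(masked, "feature_matrix"), masked$mode == "classify")
  miss <- which(is.na(masked$label))
  if (length(miss) == 0L) return(masked)
  if (length(miss) == nrow(masked$features)) {
    of_error("all labels are masked; nothing to learn from",
             "oncoforest_empty_error")
  }
  obs <- setdiff(seq_len(nrow(masked$features)), miss)
  obs_y <- droplevels(masked$label[obs])
  if (nlevels(obs_y) < 2L) {
    warning("observed labels are single-class; constant imputation",
            call. = FALSE)
    out <- masked
    out$label[miss] <- levels(obs_y)[1L]
    return(out)
  }
  X <- masked$features
  filled <- switch(method,
    knn9 = {
      nn <- nearest_neighbours(X[obs, , drop = FALSE],
                               X[miss, , drop = FALSE],
                               min(9L, length(obs)))
      obs_lab <- as.character(masked$label[obs])
      apply(nn, 1L, function(ix) names(which.max(table(obs_lab[ix]))))
    },
    lasso_logistic = {
      set.seed(derive_seed(seed, "lasso"))
      fit <- glmnet::cv.glmnet(X[obs, , drop = FALSE], masked$label[obs],
                               family = "binomial", nlambda = 100L)
      as.character(stats::predict(fit, X[miss, , drop = FALSE],
                                  s = "lambda.min", type = "class"))
    },
    cart = {
      df <- data.frame(.label = masked$label[obs],
                       X[obs, , drop = FALSE], check.names = TRUE)
      fit <- rpart::rpart(.label ~ ., data = df, method = "class")
      newd <- data.frame(X[miss, , drop = FALSE], check.names = TRUE)
      as.character(stats::predict(fit, newd, type = "class"))
    },
    rf_iterative = {
      cur <- masked$label
      # initialise with the majority class, then alternate fit/predict
      cur[miss] <- names(which.max(table(masked$label[obs])))
      prev <- NULL
      for (it in seq_len(max_iter)) {
        train <- fm_subset(masked, obs)
        train$label <- cur[obs]
        it_cfg <- cfg; it_cfg$seed <- derive_seed(seed, "rf_impute", it)
        model <- train_classifier(train, it_cfg, importance = FALSE)
        new_lab <- as.character(predict(model, X[miss, , drop = FALSE]))
        if (identical(new_lab, prev)) break
        prev <- new_lab
        cur[miss] <- new_lab
      }
      as.character(cur[miss])
    })
  out <- masked
  out$label[miss] <- filled
  stopifnot(!anyNA(out$label))
  out
}

#' Imputation robustness experiment
#'
#' For each masking fraction and imputation method: mask the labels,
#' impute them, train classifiers by k-fold cross-validation on the
#' imputed labels, and evaluate each fold on original-truth labels of
#' rows that were never masked (so the evaluation target is always
#' ground truth).  Reports the imputation accuracy (imputed vs true
#' label on the masked rows) alongside the downstream classification
#' metrics.
#'
#' @param fm classify-mode feature matrix with complete true labels.
#' @param fractions masking fractions (default `c(0.1, 0.2, 0.3, 0.4)`).
#' @param methods imputation methods (see [impute()]).
#' @param cfg an [rf_config()].
#' @param k folds for the downstream CV.
#' @return data.frame with one row per fraction x method:
#'   `fraction`, `method`, `imputation_accuracy`, `accuracy`,
#'   `sensitivity`, `specificity`, `kappa`, `n_eval`.
#' @export
imputation_experiment <- function(fm, fractions = c(0.1, 0.2, 0.3, 0.4),
                                  methods = c("knn9", "lasso_logistic"),
                                  cfg = rf_config(), k = 5L) {
  stopifnot(inherits(fm, "feature_matrix"), fm$mode == "classify")
  n <- nrow(fm$features)
  rows <- list()
  for (f in fractions) {
    plan <- mask_plan(f, seed = derive_seed(cfg$seed, "mask", f))
    mk <- mask_values(fm, plan)
    for (m in methods) {
      completed <- impute(mk$masked, m, cfg = cfg,
                          seed = derive_seed(cfg$seed, "impute", m, f))
      stopifnot(identical(completed$label[-mk$masked_rows],
                          fm$label[-mk$masked_rows]))
      imp_acc <- mean(completed$label[mk$masked_rows] ==
                        mk$truth[mk$masked_rows])
      folds <- make_folds(n, k, derive_seed(cfg$seed, "impute_cv", m, f))
      pred_all <- character(0); truth_all <- character(0)
      for (i in seq_len(k)) {
        test_idx <- folds[[i]]
        train <- fm_subset(completed, setdiff(seq_len(n), test_idx))
        eval_idx <- setdiff(test_idx, mk$masked_rows)  # never-masked rows
        if (length(eval_idx) == 0L) next
        i_cfg <- cfg
        i_cfg$seed <- derive_seed(cfg$seed, "impute_fit", m, f, i)
        model <- train_classifier(train, i_cfg, importance = FALSE)
        pred_all <- c(pred_all,
                      as.character(predict(model, fm$features[eval_idx, , drop = FALSE])))
        truth_all <- c(truth_all, as.character(fm$label[eval_idx]))
      }
      cm <- compute_metrics(pred_all, truth_all)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, method = m, imputation_accuracy = imp_acc,
        accuracy = cm$accuracy, sensitivity = cm$sensitivity,
        specificity = cm$specificity, kappa = cm$kappa, n_eval = cm$N,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
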