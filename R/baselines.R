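#' Dummy classification baselines
#'
#' Dataset-based baselines evaluated with k-fold cross-validation
#' (default 10-fold): `zero_rule` predicts the training majority class
#' for every test row; `stratified` draws labels at random with the
#' training class frequencies; `uniform` flips a fair coin; `knn9`
#' predicts the majority class of the 9 nearest training rows
#' (Euclidean over all features).
#'
#' @param fm classify-mode feature matrix.
#' @param strategy one of `"zero_rule"`, `"stratified"`, `"uniform"`,
#'   `"knn9"`.
#' @param k_folds folds (default 10).
#' @param seed integer seed for the random strategies and the folds.
#' @return list with `pooled` (a `class_metrics` over all out-of-fold
#'   predictions), `per_fold`, `mean`, `sd`.
#' @export
dummy_classifier <- function(fm, strategy = c("zero_rule", "stratified",
                                              "uniform", "knn9"),
                             k_folds = 10L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(fm, "feature_matrix"), fm$mode == "classify")
  n <- nrow(fm$features)
  folds <- make_folds(n, k_folds, seed)
  pooled_pred <- character(n)
  metrics <- vector("list", k_folds)
  for (i in seq_along(folds)) {
    test_idx <- folds[[i]]
    train_y <- fm$label[-test_idx]
    n_test <- length(test_idx)
    set.seed(derive_seed(seed, "dummy", strategy, i))
    pred <- switch(strategy,
      zero_rule = rep(names(which.max(table(train_y))), n_test),
      stratified = sample(levels(train_y), n_test, replace = TRUE,
                          prob = prop.table(table(train_y))),
      uniform = sample(levels(train_y), n_test, replace = TRUE),
      knn9 = {
        nn <- nearest_neighbours(fm$features[-test_idx, , drop = FALSE],
                                 fm$features[test_idx, , drop = FALSE], 9L)
        apply(nn, 1L, function(ix) names(which.max(table(train_y[ix]))))
      })
    pooled_pred[test_idx] <- pred
    metrics[[i]] <- compute_metrics(pred, fm$label[test_idx])
  }
  out <- summarise_class_metrics(metrics)
  out$pooled <- compute_metrics(pooled_pred, fm$label)
  out$strategy <- strategy
  out
}

#' Dummy regression baselines
#'
#' `zero_rule_mean` predicts the training-set mean log10 IC50;
#' `quantile` predicts a fixed training-set quantile `q` (5% to 95% by
#' 5%); `knn9` predicts the mean target of the 9 nearest training rows.
#' Evaluated by k-fold cross-validation, primarily through RMSE.
#'
#' @param fm regress-mode feature matrix.
#' @param strategy `"zero_rule_mean"`, `"quantile"`, or `"knn9"`.
#' @param q quantile for the quantile strategy, in \{0.05, ..., 0.95\}.
#' @param k_folds folds (default 10).
#' @param seed fold seed.
#' @return list with `pooled` (a `reg_metrics`), `per_fold` data.frame.
#' @export
dummy_regressor <- function(fm, strategy = c("zero_rule_mean", "quantile",
                                             "knn9"),
                            q = 0.5, k_folds = 10L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(fm, "feature_matrix"), fm$mode == "regress")
  if (strategy == "quantile") {
    grid <- seq(0.05, 0.95, by = 0.05)
    if (!any(abs(grid - q) < 1e-9)) {
      of_error("q must be one of 0.05, 0.10, ..., 0.95", "oncoforest_config_error")
    }
  }
  n <- nrow(fm$features)
  folds <- make_folds(n, k_folds, seed)
  pooled <- numeric(n)
  per <- vector("list", k_folds)
  for (i in seq_along(folds)) {
    test_idx <- folds[[i]]
    train_y <- fm$target[-test_idx]
    pred <- switch(strategy,
      zero_rule_mean = rep(mean(train_y), length(test_idx)),
      quantile = rep(stats::quantile(train_y, q, names = FALSE),
                     length(test_idx)),
      knn9 = {
        nn <- nearest_neighbours(fm$features[-test_idx, , drop = FALSE],
                                 fm$features[test_idx, , drop = FALSE], 9L)
        rowMeans(matrix(train_y[nn], nrow = nrow(nn)))
      })
    pooled[test_idx] <- pred
    per[[i]] <- data.frame(fold = i,
                           rmse = sqrt(mean((pred - fm$target[test_idx])^2)))
  }
  suppressWarnings(
    pooled_metrics <- regression_metrics(pooled, fm$target)
  )
  list(pooled = pooled_metrics, per_fold = do.call(rbind, per),
       strategy = strategy)
}
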