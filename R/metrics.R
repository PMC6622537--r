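#' Confusion-matrix classification metrics
#'
#' Computes the standard confusion-derived statistics for predicted vs
#' true activity classes: accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, false positive rate `FP/(TN+FP)`, negative
#' predictive value `TN/(TN+FN)`, and Cohen's kappa
#' `(p0 - pe)/(1 - pe)` with chance agreement
#' `pe = ((TP+FN)(TP+FP) + (FP+TN)(FN+TN)) / N^2`.
#' The *active* class is the positive class.  A ratio with a zero
#' denominator is reported as `NA` with a warning, never coerced to 0.
#'
#' @param predictions factor/character vector of predicted classes
#'   (`active`/`inactive`).
#' @param truth vector of true classes, same length.
#' @return a `class_metrics` object: named list with counts `TP`, `TN`,
#'   `FP`, `FN`, `N` and statistics `accuracy`, `sensitivity`,
#'   `specificity`, `fpr`, `npv`, `p0`, `pe`, `kappa`.
#' @export
#' @examples
#' compute_metrics(rep(c("active", "inactive"), c(50, 50)),
#'                 rep(c("active", "inactive"), c(50, 50)))
compute_metrics <- function(predictions, truth) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) == 0L || length(predictions) != length(truth)) {
    of_error("predictions and truth must be non-empty and equal length",
             "oncoforest_validation_error")
  }
  ok <- c("active", "inactive")
  if (!all(predictions %in% ok) || !all(truth %in% ok)) {
    of_error("classes must be 'active'/'inactive'", "oncoforest_validation_error")
  }
  tp <- sum(predictions == "active" & truth == "active")
  tn <- sum(predictions == "inactive" & truth == "inactive")
  fp <- sum(predictions == "active" & truth == "inactive")
  fn <- sum(predictions == "inactive" & truth == "active")
  n <- tp + tn + fp + fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  p0 <- (tp + tn) / n
  # products in double precision: counts can exceed sqrt(.Machine$integer.max)
  pe <- (as.numeric(tp + fn) * (tp + fp) +
           as.numeric(fp + tn) * (fn + tn)) / as.numeric(n)^2
  kappa <- if (pe == 1) {
    warning("kappa undefined (chance agreement 1); reported as NA", call. = FALSE)
    NA_real_
  } else (p0 - pe) / (1 - pe)
  structure(list(
    TP = tp, TN = tn, FP = fp, FN = fn, N = n,
    accuracy = p0,
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    fpr = ratio(fp, tn + fp, "false positive rate"),
    npv = ratio(tn, tn + fn, "negative predictive value"),
    p0 = p0, pe = pe, kappa = kappa
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "class_metrics (n = %d): accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
    "  FPR %.3f, NPV %.3f, kappa %.3f\n"),
    x$N, x$accuracy, x$sensitivity, x$specificity, x$fpr, x$npv, x$kappa))
  invisible(x)
}

#' @export
as.data.frame.class_metrics <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Regression metrics for predicted log10 IC50
#'
#' Root-mean-square error (log10 IC50 units), Pearson correlation and
#' Spearman rank correlation (average ranks on ties).  Correlations for
#' a constant vector are undefined and reported as `NA` with a warning.
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return a `reg_metrics` object: list with `rmse`, `pearson_r`,
#'   `spearman_rho`, `n`.
#' @export
regression_metrics <- function(predicted, observed) {
  if (length(predicted) == 0L || length(predicted) != length(observed)) {
    of_error("predicted and observed must be non-empty and equal length",
             "oncoforest_validation_error")
  }
  rmse <- sqrt(mean((predicted - observed)^2))
  safe_cor <- function(method) {
    if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
      warning(sprintf("%s correlation undefined for constant input; reported as NA",
                      method), call. = FALSE)
      return(NA_real_)
    }
    stats::cor(predicted, observed, method = method)
  }
  structure(list(rmse = rmse,
                 pearson_r = safe_cor("pearson"),
                 spearman_rho = safe_cor("spearman"),
                 n = length(predicted)),
            class = "reg_metrics")
}

#' @export
print.reg_metrics <- function(x, ...) {
  cat(sprintf("reg_metrics (n = %d): RMSE %.3f, Pearson %.3f, Spearman %.3f\n",
              x$n, x$rmse, x$pearson_r, x$spearman_rho))
  invisible(x)
}

#' @export
as.data.frame.reg_metrics <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Trapezoid area under an ROC point set
#'
#' The ROC here is traced by sweeping the IC50 activity cutoff (not a
#' score threshold): each cutoff contributes one (FPR, sensitivity)
#' point.  The curve is augmented with the (0,0) and (1,1) anchors,
#' sorted by FPR (then TPR), and integrated by the trapezoid rule.
#'
#' @param fpr,tpr numeric vectors of false positive rates and
#'   sensitivities, each in `[0, 1]`.
#' @return the AUC, a number in `[0, 1]`.
#' @export
#' @examples
#' trapezoid_auc(c(0, 0.2, 1), c(0, 0.6, 1))  # 0.70
trapezoid_auc <- function(fpr, tpr) {
  stopifnot(length(fpr) == length(tpr))
  keep <- is.finite(fpr) & is.finite(tpr)
  fpr <- fpr[keep]; tpr <- tpr[keep]
  if (any(fpr < 0 | fpr > 1 | tpr < 0 | tpr > 1)) {
    of_error("ROC coordinates must lie in [0, 1]", "oncoforest_validation_error")
  }
  x <- c(0, fpr, 1); y <- c(0, tpr, 1)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# internal: aggregate a list of class_metrics into per-fold, mean, sd
summarise_class_metrics <- function(metrics_list, id_col = "fold") {
  per <- do.call(rbind, lapply(seq_along(metrics_list), function(i) {
    cbind(stats::setNames(data.frame(i), id_col),
          as.data.frame(metrics_list[[i]]))
  }))
  stat_cols <- c("accuracy", "sensitivity", "specificity", "fpr", "npv", "kappa")
  list(per_fold = per,
       mean = colMeans(per[, stat_cols, drop = FALSE], na.rm = TRUE),
       sd = vapply(per[, stat_cols, drop = FALSE], stats::sd,
                   numeric(1L), na.rm = TRUE))
}
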