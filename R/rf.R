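#' Random-forest configuration
#'
#' @param n_trees number of trees (default 500, the screening-scale
#'   setting used throughout).
#' @param m_try features tried per split; `NULL` (default) means
#'   `round(sqrt(n_features))`, which gives 37 for the full 1361-feature
#'   matrix.
#' @param seed integer seed; every fit derives its own sub-seed from it.
#' @param num_threads threads for ranger (default 1: fits are then
#'   bit-reproducible for a fixed seed).
#' @return an `rf_config` object.
#' @export
rf_config <- function(n_trees = 500L, m_try = NULL, seed = 1L,
                      num_threads = 1L) {
  if (n_trees < 1L) of_error("n_trees must be >= 1", "oncoforest_config_error")
  structure(list(n_trees = as.integer(n_trees),
                 m_try = if (is.null(m_try)) NULL else as.integer(m_try),
                 seed = as.integer(seed),
                 num_threads = as.integer(num_threads)),
            class = "rf_config")
}

# internal: resolve mtry for a given feature count
resolve_mtry <- function(cfg, n_features) {
  m <- cfg$m_try %||% max(1L, round(sqrt(n_features)))
  if (m < 1L || m > n_features) {
    of_error(sprintf("m_try = %d outside [1, %d]", m, n_features),
             "oncoforest_config_error")
  }
  m
}

#' Train a random-forest activity classifier
#'
#' Fits a ranger forest (Gini split rule, impurity importance) on a
#' classify-mode feature matrix.  Deterministic for a fixed
#' configuration seed.
#'
#' @param fm a classify-mode [assemble_matrix()] result; both classes
#'   must be present.
#' @param cfg an [rf_config()].
#' @param importance compute per-feature Gini (impurity) importance
#'   (default TRUE; skipping it saves a little time).
#' @return an `rf_classifier`: opaque handle exposing [predict()] and
#'   `$importance` (named non-negative vector over all features).
#' @export
train_classifier <- function(fm, cfg = rf_config(), importance = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "rf_config"))
  if (fm$mode != "classify") of_error("matrix is not in classify mode",
                                      "oncoforest_validation_error")
  y <- droplevels(fm$label)
  if (nlevels(y) < 2L) {
    of_error("training data contain a single class; cannot fit a classifier",
             "oncoforest_degenerate_error")
  }
  fit <- ranger::ranger(
    x = fm$features, y = fm$label,
    num.trees = cfg$n_trees, mtry = resolve_mtry(cfg, ncol(fm$features)),
    importance = if (importance) "impurity" else "none",
    seed = cfg$seed, num.threads = cfg$num_threads,
    verbose = FALSE
  )
  structure(list(fit = fit,
                 feature_names = colnames(fm$features),
                 gene_ids = fm$gene_ids,
                 importance = if (importance) fit$variable.importance else NULL,
                 cfg = cfg),
            class = "rf_classifier")
}

#' @export
predict.rf_classifier <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "feature_matrix")) newdata$features else newdata
  stopifnot(identical(colnames(feats), object$feature_names))
  # fixed prediction seed: vote ties would otherwise break at random
  p <- stats::predict(object$fit, data = feats, seed = object$cfg$seed,
                      num.threads = object$cfg$num_threads)$predictions
  factor(as.character(p), levels = c("active", "inactive"))
}

#' Train a random-forest log10 IC50 regressor
#'
#' @param fm a regress-mode [assemble_matrix()] result (conventionally
#'   built on the top-50 importance gene subset plus all chemical
#'   descriptors).
#' @param cfg an [rf_config()].
#' @return an `rf_regressor` handle exposing [predict()].
#' @export
train_regressor <- function(fm, cfg = rf_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "rf_config"))
  if (fm$mode != "regress") of_error("matrix is not in regress mode",
                                     "oncoforest_validation_error")
  if (stats::sd(fm$target) == 0) {
    warning("constant regression target; predictions will be constant",
            call. = FALSE)
  }
  fit <- ranger::ranger(
    x = fm$features, y = fm$target,
    num.trees = cfg$n_trees, mtry = resolve_mtry(cfg, ncol(fm$features)),
    seed = cfg$seed, num.threads = cfg$num_threads, verbose = FALSE
  )
  structure(list(fit = fit, feature_names = colnames(fm$features),
                 gene_ids = fm$gene_ids, cfg = cfg),
            class = "rf_regressor")
}

#' @export
predict.rf_regressor <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "feature_matrix")) newdata$features else newdata
  stopifnot(identical(colnames(feats), object$feature_names))
  stats::predict(object$fit, data = feats, seed = object$cfg$seed,
                 num.threads = object$cfg$num_threads)$predictions
}
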