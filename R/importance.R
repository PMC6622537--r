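#' Rank oncogene mutation features by Gini importance
#'
#' Trains one forest on the full classify-mode matrix and extracts the
#' impurity (Gini) importance of the gene-bit columns, sorted in
#' decreasing order (ties broken by gene identifier).  Absolute
#' importance magnitudes are implementation-dependent; ranks are the
#' meaningful output.
#'
#' @param fm classify-mode feature matrix.
#' @param cfg an [rf_config()].
#' @return data.frame with columns `feature_id`, `gini_importance`,
#'   `rank` (1 = most important), restricted to gene columns.
#' @export
rank_gene_importance <- function(fm, cfg = rf_config()) {
  stopifnot(inherits(fm, "feature_matrix"), fm$mode == "classify")
  model <- train_classifier(fm, cfg, importance = TRUE)
  imp <- model$importance[fm$gene_ids]
  ord <- order(-imp, names(imp))
  data.frame(feature_id = names(imp)[ord],
             gini_importance = unname(imp[ord]),
             rank = seq_along(imp),
             stringsAsFactors = FALSE)
}

#' Per-drug top-ranking oncogenes
#'
#' For each drug (with at least `min_records` records and both classes
#' present), trains a forest on that drug's rows using the gene columns
#' only — within one drug every chemical descriptor is constant and
#' carries no information — and calls as *top-ranking* the genes whose
#' Gini importance exceeds the mean plus `sd_mult` population standard
#' deviations of that drug's gene importances.
#'
#' @param panel,drugs,sens filtered input tables.
#' @param cfg an [rf_config()].
#' @param labeling a [labeling_config()].
#' @param sd_mult threshold multiplier (default 2).
#' @param min_records skip drugs with fewer records (default 10).
#' @return list with `per_drug` (named list of character vectors of
#'   top genes), `gene_counts` (named integer vector: for each gene, the
#'   number of drugs for which it is top-ranking), and `skipped`
#'   (drug ids skipped with a warning).
#' @export
per_drug_top_genes <- function(panel, drugs, sens, cfg = rf_config(),
                               labeling = labeling_config(), sd_mult = 2,
                               min_records = 10L) {
  fm <- assemble_matrix(panel, drugs, sens, NULL, labeling, "classify")
  genes <- fm$gene_ids
  per_drug <- list()
  skipped <- character(0)
  for (d in drugs$drug_ids) {
    rows <- which(fm$drug_id == d)
    y <- droplevels(fm$label[rows])
    if (length(rows) < min_records || nlevels(y) < 2L) {
      warning(sprintf("drug %s skipped (%d records, %d class(es))",
                      d, length(rows), nlevels(y)), call. = FALSE)
      skipped <- c(skipped, d)
      next
    }
    sub <- fm_subset(fm, rows)
    sub$features <- sub$features[, genes, drop = FALSE]
    d_cfg <- cfg
    d_cfg$seed <- derive_seed(cfg$seed, "per_drug", d)
    d_cfg$m_try <- cfg$m_try %||% max(1L, round(sqrt(length(genes))))
    model <- train_classifier(sub, d_cfg, importance = TRUE)
    imp <- model$importance[genes]
    mu <- mean(imp)
    sd_pop <- sqrt(mean((imp - mu)^2))
    per_drug[[d]] <- names(imp)[imp > mu + sd_mult * sd_pop]
  }
  counts <- table(factor(unlist(per_drug), levels = genes))
  list(per_drug = per_drug,
       gene_counts = stats::setNames(as.integer(counts), genes),
       skipped = skipped)
}

#' Minimal oncogene-set search
#'
#' Ranks all genes once by global Gini importance, then for each subset
#' size `N` retains only the top-`N` genes plus all chemical
#' descriptors, rebuilds the matrix and runs [kfold_cv()].  Traces how
#' classification performance degrades as the mutation panel shrinks.
#'
#' @param panel,drugs,sens filtered input tables.
#' @param cfg an [rf_config()].
#' @param labeling a [labeling_config()].
#' @param subset_sizes gene-subset sizes; the default grid merges the
#'   5-to-100-by-5 ladder with the coarser 125/110/95/80/65/50/40/30
#'   series (`N = 0` runs the chemistry-only ablation).
#' @param k folds per size.
#' @param ranking optionally a precomputed [rank_gene_importance()]
#'   table (saves one forest fit).
#' @return list with `metrics` (data.frame: size, accuracy, sensitivity,
#'   specificity, kappa), `ranking` (the global importance table), and
#'   `runs` (per-size kfold_cv results).
#' @export
minimal_gene_search <- function(panel, drugs, sens, cfg = rf_config(),
                                labeling = labeling_config(),
                                subset_sizes = default_subset_sizes(),
                                k = 5L, ranking = NULL) {
  if (length(subset_sizes) == 0L) of_error("empty subset size list",
                                           "oncoforest_config_error")
  n_genes <- ncol(panel$mutation)
  if (any(subset_sizes > n_genes)) {
    of_error("subset size exceeds total gene count", "oncoforest_config_error")
  }
  if (is.null(ranking)) {
    fm_full <- assemble_matrix(panel, drugs, sens, NULL, labeling, "classify")
    rank_cfg <- cfg; rank_cfg$seed <- derive_seed(cfg$seed, "global_rank")
    ranking <- rank_gene_importance(fm_full, rank_cfg)
  }
  runs <- list()
  rows <- lapply(sort(unique(as.integer(subset_sizes)), decreasing = TRUE),
                 function(N) {
    subset <- if (N > 0L) ranking$feature_id[seq_len(N)] else character(0)
    fm <- assemble_matrix(panel, drugs, sens, subset, labeling, "classify")
    res <- kfold_cv(fm, cfg, k = k)
    runs[[as.character(N)]] <<- res
    data.frame(size = N,
               accuracy = res$mean[["accuracy"]],
               sensitivity = res$mean[["sensitivity"]],
               specificity = res$mean[["specificity"]],
               kappa = res$mean[["kappa"]])
  })
  list(metrics = do.call(rbind, rows), ranking = ranking, runs = runs)
}

#' @rdname minimal_gene_search
#' @export
default_subset_sizes <- function() {
  sort(unique(c(seq(5L, 100L, by = 5L), c(125L, 110L, 95L, 80L, 65L, 50L, 40L, 30L))))
}
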