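#' Per-gene mutation information entropy
#'
#' Binary entropy (in bits) of each gene's mutation frequency across
#' cell lines: `H = -p log2 p - (1-p) log2(1-p)` with `p` the mutated
#' fraction; `H(0) = H(1) = 0` by convention.  Genes whose mutated and
#' unmutated cell-line counts are closest carry the most information and
#' are preferred for the panel.
#'
#' @param panel a filtered [oncogene_panel()] (no missing statuses).
#' @return named numeric vector of entropies, one per gene.
#' @export
#' @examples
#' p <- oncogene_panel(matrix(c(0, 1, 1, 0), 2, 2,
#'   dimnames = list(c("c1", "c2"), c("g1", "g2"))))
#' mutation_entropy(p)
mutation_entropy <- function(panel) {
  stopifnot(inherits(panel, "oncogene_panel"))
  m <- panel$mutation
  if (nrow(m) == 0L || ncol(m) == 0L) {
    of_error("empty panel", "oncoforest_empty_error")
  }
  # work from integer counts: genes whose mutated/unmutated split is
  # mathematically identical then get bitwise-identical entropies, so
  # the documented lexicographic tie-break applies exactly
  n_obs <- colSums(!is.na(m))
  cnt <- colSums(m == 1L, na.rm = TRUE)
  q <- pmin(cnt, n_obs - cnt) / n_obs
  h <- ifelse(q <= 0, 0, -q * log2(q) - (1 - q) * log2(1 - q))
  stats::setNames(h, colnames(m))
}

#' Select the genes with highest mutation entropy
#'
#' Returns the `k` genes with the largest binary mutation entropy,
#' in descending entropy order; ties are broken lexicographically by
#' gene identifier.
#'
#' @param panel an [oncogene_panel()].
#' @param k number of genes to keep, `1 <= k <= ncol(panel)`.
#' @return character vector of `k` gene identifiers.
#' @export
select_top_entropy_genes <- function(panel, k) {
  ent <- mutation_entropy(panel)
  if (k < 1L || k > length(ent)) {
    of_error(sprintf("k must lie in [1, %d]", length(ent)),
             "oncoforest_config_error")
  }
  ord <- order(-ent, names(ent))
  names(ent)[ord][seq_len(k)]
}

#' Labeling configuration for activity classification
#'
#' @param cutoff_molar IC50 activity threshold in molar, strictly
#'   positive.  A record is *active* when its IC50 is at or below the
#'   cutoff (inclusive); 1 uM (`1e-6`) is the conventional screening
#'   threshold.
#' @return an object of class `labeling_config`.
#' @export
labeling_config <- function(cutoff_molar = 1e-6) {
  if (!is.finite(cutoff_molar) || cutoff_molar <= 0) {
    of_error("cutoff must be a strictly positive molar concentration",
             "oncoforest_config_error")
  }
  structure(list(cutoff_molar = cutoff_molar,
                 cutoff_log10m = log10(cutoff_molar)),
            class = "labeling_config")
}

#' Assemble the per-pair feature matrix
#'
#' One row per observed (drug, cell line) record: the cell line's
#' mutation bits for `gene_subset` joined with the drug's full chemical
#' fingerprint.  In `classify` mode the row is labeled *active* when
#' log10 IC50 is at or below the cutoff (inclusive); in `regress` mode
#' the raw log10 IC50 is attached as the target.
#'
#' @param panel a filtered [oncogene_panel()].
#' @param drugs a [drug_library()].
#' @param sens a [sensitivity_table()] with only observed records (the
#'   output of [filter_dataset()]).
#' @param gene_subset genes to include, a subset of the panel's genes;
#'   defaults to all panel genes.
#' @param labeling a [labeling_config()] (classify mode only).
#' @param mode `"classify"` or `"regress"`.
#' @return an object of class `feature_matrix`: list with `drug_id`,
#'   `cell_line_id`, `features` (numeric matrix, gene columns first),
#'   `gene_ids`, and `label` (factor active/inactive) or `target`
#'   (numeric log10 IC50).
#' @export
assemble_matrix <- function(panel, drugs, sens, gene_subset = NULL,
                            labeling = labeling_config(),
                            mode = c("classify", "regress")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "oncogene_panel"), inherits(drugs, "drug_library"),
            inherits(sens, "sensitivity_table"))
  if (any(!sens$observed)) {
    of_error("assemble_matrix requires observed records only; run filter_dataset first",
             "oncoforest_validation_error")
  }
  validate_tables(panel, drugs, sens)
  gene_subset <- gene_subset %||% colnames(panel$mutation)
  missing_genes <- setdiff(gene_subset, colnames(panel$mutation))
  if (length(missing_genes) > 0L) {
    of_error(sprintf("gene_subset contains unknown gene(s): %s",
                     paste(utils::head(missing_genes, 3L), collapse = ", ")),
             "oncoforest_reference_error")
  }
  cell_idx <- match(sens$cell_line_id, rownames(panel$mutation))
  drug_idx <- match(sens$drug_id, drugs$drug_ids)
  gm <- panel$mutation[, gene_subset, drop = FALSE]
  storage.mode(gm) <- "double"
  features <- cbind(gm[cell_idx, , drop = FALSE],
                    drugs$fingerprints[drug_idx, , drop = FALSE])
  rownames(features) <- NULL
  out <- list(drug_id = sens$drug_id, cell_line_id = sens$cell_line_id,
              features = features, gene_ids = gene_subset, mode = mode)
  if (mode == "classify") {
    stopifnot(inherits(labeling, "labeling_config"))
    out$label <- factor(ifelse(sens$log10_ic50 <= labeling$cutoff_log10m,
                               "active", "inactive"),
                        levels = c("active", "inactive"))
    out$cutoff_molar <- labeling$cutoff_molar
  } else {
    out$target <- sens$log10_ic50
  }
  structure(out, class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix (%s): %d rows x %d features (%d gene bits + %d chemical)\n",
              x$mode, nrow(x$features), ncol(x$features),
              length(x$gene_ids), ncol(x$features) - length(x$gene_ids)))
  if (x$mode == "classify") {
    tab <- table(x$label)
    cat(sprintf("  labels: %d active / %d inactive (cutoff %.3g M)\n",
                tab[["active"]], tab[["inactive"]], x$cutoff_molar))
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$features)

# internal: row-subset a feature matrix
fm_subset <- function(fm, rows) {
  out <- fm
  out$drug_id <- fm$drug_id[rows]
  out$cell_line_id <- fm$cell_line_id[rows]
  out$features <- fm$features[rows, , drop = FALSE]
  if (!is.null(fm$label)) out$label <- fm$label[rows]
  if (!is.null(fm$target)) out$target <- fm$target[rows]
  out
}

#' Write a feature matrix to CSV
#'
#' Serialized with the label (or regression target) as the first data
#' column after the identifiers, mirroring the deposited screening
#' matrix layout.
#'
#' @param fm a [assemble_matrix()] result.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  lead <- data.frame(drug_id = fm$drug_id, cell_line_id = fm$cell_line_id,
                     stringsAsFactors = FALSE)
  if (fm$mode == "classify") lead$label <- as.character(fm$label)
  else lead$target <- fm$target
  utils::write.csv(cbind(lead, as.data.frame(fm$features, check.names = FALSE)),
                   path, row.names = FALSE, na = "")
  invisible(path)
}
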