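#' Oncogene mutation panel
#'
#' A binary cell line x gene mutation matrix: entry 1 means the gene
#' carries any sequence variation in that cell line, 0 means no mutation
#' was observed, NA means mutation status was not determined.
#'
#' @param mutation numeric or integer matrix with values in \{0, 1, NA\};
#'   rownames are cell-line identifiers, colnames gene identifiers (both
#'   may instead be supplied via `cell_line_ids` / `gene_ids`).
#' @param cell_line_ids,gene_ids optional identifier vectors overriding
#'   the dimnames.
#' @return an object of class `oncogene_panel`.
#' @export
oncogene_panel <- function(mutation, cell_line_ids = rownames(mutation),
                           gene_ids = colnames(mutation)) {
  mutation <- as.matrix(mutation)
  if (is.null(cell_line_ids) || is.null(gene_ids)) {
    of_error("oncogene_panel requires cell line and gene identifiers",
             "oncoforest_validation_error")
  }
  cell_line_ids <- as.character(cell_line_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(cell_line_ids)) {
    of_error("duplicate cell line identifiers in mutation panel",
             "oncoforest_validation_error")
  }
  if (anyDuplicated(gene_ids)) {
    of_error("duplicate gene identifiers in mutation panel",
             "oncoforest_validation_error")
  }
  if (length(cell_line_ids) != nrow(mutation) ||
      length(gene_ids) != ncol(mutation)) {
    of_error("identifier lengths do not match mutation matrix dimensions",
             "oncoforest_validation_error")
  }
  storage.mode(mutation) <- "integer"
  bad <- which(!is.na(mutation) & !(mutation %in% c(0L, 1L)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    of_error(sprintf(
      "mutation status must be 0, 1 or missing; first offender: cell '%s', gene '%s'",
      cell_line_ids[bad[1L, 1L]], gene_ids[bad[1L, 2L]]),
      "oncoforest_format_error")
  }
  dimnames(mutation) <- list(cell_line_ids, gene_ids)
  structure(list(mutation = mutation), class = "oncogene_panel")
}

#' @export
print.oncogene_panel <- function(x, ...) {
  m <- x$mutation
  cat(sprintf("oncogene_panel: %d cell lines x %d genes, %d mutations, %d missing statuses\n",
              nrow(m), ncol(m), sum(m == 1L, na.rm = TRUE), sum(is.na(m))))
  invisible(x)
}

#' @export
dim.oncogene_panel <- function(x) dim(x$mutation)

#' Drug library with chemical fingerprints
#'
#' Drug identifiers, optional SMILES structures, and a per-drug numeric
#' fingerprint: 192 continuous 2-D descriptors followed by 1024 circular
#' fingerprint bits (1216 columns in total by default).
#'
#' @param drug_ids character vector of unique identifiers.
#' @param smiles optional character vector of SMILES strings (NA allowed).
#' @param fingerprints numeric matrix, one row per drug; the trailing
#'   `n_bits` columns must be 0/1, the leading continuous block finite.
#' @param n_bits number of fingerprint bit columns at the end of the
#'   matrix (default 1024).
#' @return an object of class `drug_library`.
#' @export
drug_library <- function(drug_ids, fingerprints, smiles = NULL, n_bits = 1024L) {
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(drug_ids)) {
    of_error("duplicate drug identifiers", "oncoforest_validation_error")
  }
  fingerprints <- as.matrix(fingerprints)
  storage.mode(fingerprints) <- "double"
  if (nrow(fingerprints) != length(drug_ids)) {
    of_error("fingerprint row count does not match drug count",
             "oncoforest_validation_error")
  }
  if (n_bits > ncol(fingerprints)) {
    of_error("n_bits exceeds fingerprint length", "oncoforest_validation_error")
  }
  n_cont <- ncol(fingerprints) - n_bits
  if (n_cont > 0L && any(!is.finite(fingerprints[, seq_len(n_cont), drop = FALSE]))) {
    of_error("continuous descriptor block contains non-finite values",
             "oncoforest_format_error")
  }
  if (n_bits > 0L) {
    bits <- fingerprints[, n_cont + seq_len(n_bits), drop = FALSE]
    if (any(!(bits %in% c(0, 1)))) {
      of_error("fingerprint bit section must contain only 0/1",
               "oncoforest_format_error")
    }
  }
  if (is.null(colnames(fingerprints))) {
    colnames(fingerprints) <- sprintf("fp_%04d", seq_len(ncol(fingerprints)))
  }
  rownames(fingerprints) <- drug_ids
  if (!is.null(smiles)) {
    stopifnot(length(smiles) == length(drug_ids))
    smiles <- as.character(smiles)
  }
  structure(list(drug_ids = drug_ids, smiles = smiles,
                 fingerprints = fingerprints, n_bits = as.integer(n_bits)),
            class = "drug_library")
}

#' @export
print.drug_library <- function(x, ...) {
  cat(sprintf("drug_library: %d drugs, fingerprint length %d (%d continuous + %d bits)%s\n",
              length(x$drug_ids), ncol(x$fingerprints),
              ncol(x$fingerprints) - x$n_bits, x$n_bits,
              if (is.null(x$smiles)) "" else ", SMILES present"))
  invisible(x)
}

#' Drug sensitivity table
#'
#' Long-form (drug, cell line, log10 IC50 in molar) records.  An
#' unobserved record keeps its row but has `observed = FALSE` and a
#' missing `log10_ic50`.
#'
#' @param records data.frame with columns `drug_id`, `cell_line_id`,
#'   `log10_ic50` (NA for unobserved records) and optionally `observed`.
#' @return an object of class `sensitivity_table` (a data.frame).
#' @export
sensitivity_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("drug_id", "cell_line_id", "log10_ic50")
  if (!all(need %in% names(records))) {
    of_error(paste("sensitivity table needs columns:", paste(need, collapse = ", ")),
             "oncoforest_format_error")
  }
  records$drug_id <- as.character(records$drug_id)
  records$cell_line_id <- as.character(records$cell_line_id)
  records$log10_ic50 <- as.numeric(records$log10_ic50)
  if (is.null(records$observed)) {
    records$observed <- !is.na(records$log10_ic50)
  }
  records$observed <- as.logical(records$observed)
  if (any(records$observed & !is.finite(records$log10_ic50))) {
    of_error("observed records must carry a finite log10 IC50",
             "oncoforest_format_error")
  }
  key <- paste(records$drug_id, records$cell_line_id, sep = "\r")
  if (anyDuplicated(key)) {
    of_error("duplicate (drug, cell line) pair in sensitivity table",
             "oncoforest_validation_error")
  }
  records <- records[, c("drug_id", "cell_line_id", "log10_ic50", "observed")]
  class(records) <- c("sensitivity_table", "data.frame")
  records
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("sensitivity_table: %d records (%d observed, %d missing), %d drugs x %d cell lines\n",
              nrow(x), sum(x$observed), sum(!x$observed),
              length(unique(x$drug_id)), length(unique(x$cell_line_id))))
  invisible(x)
}

## ---- CSV reading/writing -------------------------------------------------
## Dialect: comma-separated, UTF-8, mandatory header, empty/NA = missing.

#' Read an oncogene mutation panel from CSV
#'
#' Expected schema: header row of gene ids, first column `cell_line_id`,
#' remaining cells in \{0, 1, NA/empty\}.
#'
#' @param path CSV file path.
#' @return an [oncogene_panel()].
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) of_error("panel CSV needs cell id column plus gene columns",
                              "oncoforest_format_error")
  ids <- df[[1L]]
  genes <- names(df)[-1L]
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m == ""] <- NA_character_
  bad <- which(!is.na(m) & !(m %in% c("0", "1")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    of_error(sprintf("invalid mutation value '%s' at row %d (cell '%s'), column '%s'",
                     m[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                     ids[bad[1L, 1L]], genes[bad[1L, 2L]]),
             "oncoforest_format_error")
  }
  storage.mode(m) <- "integer"
  oncogene_panel(m, cell_line_ids = ids, gene_ids = genes)
}

#' Write an oncogene mutation panel to CSV
#' @param panel an [oncogene_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "oncogene_panel"))
  df <- data.frame(cell_line_id = rownames(panel$mutation),
                   panel$mutation, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a drug library from CSV
#'
#' Schema: `drug_id`, optional `smiles`, then fingerprint columns
#' `fp_0001 ... fp_NNNN` (continuous descriptors first, bits last).
#'
#' @param path CSV file path.
#' @param n_bits number of trailing bit columns (default 1024, capped at
#'   the fingerprint length).
#' @return a [drug_library()].
#' @export
read_drugs <- function(path, n_bits = 1024L) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"drug_id" %in% names(df)) {
    of_error("drug CSV must contain a drug_id column", "oncoforest_format_error")
  }
  fp_cols <- grep("^fp_", names(df), value = TRUE)
  if (length(fp_cols) == 0L) {
    of_error("drug CSV contains no fingerprint columns (fp_*)",
             "oncoforest_format_error")
  }
  fp <- as.matrix(df[, fp_cols, drop = FALSE])
  if (!is.numeric(fp)) of_error("fingerprint columns must be numeric",
                                "oncoforest_format_error")
  drug_library(df$drug_id, fp,
               smiles = if ("smiles" %in% names(df)) df$smiles else NULL,
               n_bits = min(as.integer(n_bits), ncol(fp)))
}

#' Write a drug library to CSV
#' @param drugs a [drug_library()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_drugs <- function(drugs, path) {
  stopifnot(inherits(drugs, "drug_library"))
  df <- data.frame(drug_id = drugs$drug_ids, stringsAsFactors = FALSE)
  if (!is.null(drugs$smiles)) df$smiles <- drugs$smiles
  df <- cbind(df, as.data.frame(drugs$fingerprints, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sensitivity table from CSV
#'
#' Schema: `drug_id`, `cell_line_id`, `log10_ic50` (empty field =
#' unobserved record, loaded with `observed = FALSE`).
#'
#' @param path CSV file path.
#' @return a [sensitivity_table()].
#' @export
read_sensitivity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sensitivity_table(df)
}

#' Write a sensitivity table to CSV
#' @param sens a [sensitivity_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(sens, path) {
  stopifnot(inherits(sens, "sensitivity_table"))
  df <- as.data.frame(sens)
  df$log10_ic50 <- ifelse(df$observed,
                          format(df$log10_ic50, digits = 15, trim = TRUE,
                                 scientific = FALSE), "")
  df$observed <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Check referential integrity across the three tables
#'
#' @param panel an [oncogene_panel()].
#' @param drugs a [drug_library()] (or NULL to skip drug checks).
#' @param sens a [sensitivity_table()].
#' @return TRUE invisibly; errors on an unknown drug or cell reference.
#' @export
validate_tables <- function(panel, drugs = NULL, sens) {
  bad_cell <- setdiff(sens$cell_line_id, rownames(panel$mutation))
  if (length(bad_cell) > 0L) {
    of_error(sprintf("sensitivity table references unknown cell line(s): %s",
                     paste(utils::head(bad_cell, 3L), collapse = ", ")),
             "oncoforest_reference_error")
  }
  if (!is.null(drugs)) {
    bad_drug <- setdiff(sens$drug_id, drugs$drug_ids)
    if (length(bad_drug) > 0L) {
      of_error(sprintf("sensitivity table references unknown drug(s): %s",
                       paste(utils::head(bad_drug, 3L), collapse = ", ")),
               "oncoforest_reference_error")
    }
  }
  invisible(TRUE)
}

#' Apply the dataset-level filtering rules
#'
#' Drops every cell line whose mutation status is missing for at least
#' `max_missing_genes` genes, removes all unobserved sensitivity records
#' and all records referencing dropped cell lines, and codes the
#' remaining sporadic missing mutation statuses as 0 (absence of
#' evidence of a mutation).
#'
#' @param panel an [oncogene_panel()].
#' @param sens a [sensitivity_table()].
#' @param max_missing_genes drop threshold (default 20): a cell line is
#'   removed when it has `>= max_missing_genes` genes with missing status.
#' @return list with elements `panel` and `sens`, both filtered.
#' @export
filter_dataset <- function(panel, sens, max_missing_genes = 20L) {
  stopifnot(inherits(panel, "oncogene_panel"), inherits(sens, "sensitivity_table"))
  validate_tables(panel, sens = sens)
  n_missing <- rowSums(is.na(panel$mutation))
  keep_cells <- n_missing < max_missing_genes
  m <- panel$mutation[keep_cells, , drop = FALSE]
  m[is.na(m)] <- 0L
  keep_rec <- sens$observed & sens$cell_line_id %in% rownames(m)
  out_sens <- sens[keep_rec, , drop = FALSE]
  if (nrow(m) == 0L || nrow(out_sens) == 0L) {
    of_error("no data remain after filtering", "oncoforest_empty_error")
  }
  rownames(out_sens) <- NULL
  class(out_sens) <- c("sensitivity_table", "data.frame")
  list(panel = oncogene_panel(m), sens = out_sens)
}

#' Save / load a fitted model with a format-version guard
#'
#' Models are serialized together with a format version and the feature
#' schema; loading refuses a blob written by an incompatible version
#' rather than silently mispredicting.
#'
#' @param object a fitted `rf_classifier` or `rf_regressor`.
#' @param path destination file.
#' @return `path` invisibly (`save_model`); the fitted object (`load_model`).
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, c("rf_classifier", "rf_regressor")))
  blob <- list(format_version = 1L,
               package_version = as.character(utils::packageVersion("oncoforest")),
               schema = object$feature_names,
               payload = object)
  saveRDS(blob, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  if (!identical(blob$format_version, 1L)) {
    of_error(sprintf("model blob format version %s is not supported",
                     format(blob$format_version)), "oncoforest_version_error")
  }
  blob$payload
}
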