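#' Ground-truth model for synthetic screening data
#'
#' Defines a GDSC-like generative model from which mutation panels, drug
#' fingerprints and log10 IC50 tables are drawn.  The sensitivity surface
#' is
#' \deqn{y(d,c) = \mu + \alpha_d + \beta_c +
#'   \sum_{g,f} \gamma_{gf}\, \mathrm{mut}(c,g)\, \mathrm{fp}(d,f) + \epsilon,}
#' with \eqn{\epsilon \sim N(0, \sigma^2)}, clipped to the observed
#' screening range `[clip_lo, clip_hi]` of log10 molar IC50.  The planted
#' gene-by-chemistry interaction coefficients are the recoverable signal
#' that downstream validation (importance ranking, minimal gene sets,
#' leave-drug-out generalization) is checked against.
#'
#' Defaults are the desk-scale preset: 300 cell lines x 40 drugs x 145
#' genes (12,000 records), 10 causal genes each interacting with 8
#' fingerprint bits at effect magnitude 0.25, noise sd 0.5 log10 units,
#' baseline centred on the 1 uM cutoff.  The default variance
#' decomposition mirrors real screens: drug-to-drug potency differences
#' (offset sd 1.5) dominate, cell offsets and gene-by-chemistry
#' interactions are moderate.
#'
#' @param n_cells,n_drugs,n_genes panel dimensions.
#' @param n_causal_genes number of genes with planted interaction effects.
#' @param bits_per_gene fingerprint bits interacting with each causal gene.
#' @param effect_size magnitude of each interaction coefficient
#'   (log10 IC50 units; signs drawn at random).
#' @param noise_sd residual sd of log10 IC50 (> 0).
#' @param baseline mean log10 molar IC50 (`mu`); the default -6 centres
#'   the surface on the 1 uM activity cutoff.
#' @param drug_offset_sd,cell_offset_sd sds of the per-drug and per-cell
#'   random offsets.
#' @param n_descriptors,n_bits fingerprint layout (192 continuous + 1024
#'   bits by default).
#' @param missing_fraction fraction of records flagged unobserved,
#'   missing completely at random.
#' @param clip_lo,clip_hi clipping bounds for log10 molar IC50; defaults
#'   are the empirical screening range (5e-11 M to 0.4 M).
#' @param seed integer seed fixing every random draw of the model and of
#'   [generate_dataset()].
#' @return an object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(n_cells = 300L, n_drugs = 40L, n_genes = 145L,
                               n_causal_genes = 10L, bits_per_gene = 8L,
                               effect_size = 0.25, noise_sd = 0.5,
                               baseline = -6, drug_offset_sd = 1.5,
                               cell_offset_sd = 0.3,
                               n_descriptors = 192L, n_bits = 1024L,
                               missing_fraction = 0, clip_lo = -10.3,
                               clip_hi = -0.4, seed = 1L) {
  if (noise_sd <= 0) of_error("noise_sd must be > 0", "oncoforest_config_error")
  if (n_causal_genes > n_genes) {
    of_error("more causal genes than genes", "oncoforest_config_error")
  }
  if (bits_per_gene * n_causal_genes > n_bits) {
    of_error("more causal bits than fingerprint bits", "oncoforest_config_error")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    of_error("missing_fraction must lie in [0, 1)", "oncoforest_config_error")
  }
  if (clip_lo >= clip_hi) of_error("clip_lo must be < clip_hi",
                                   "oncoforest_config_error")
  rng <- local({ set.seed(derive_seed(seed, "ground_truth")); list(
    mutation_freqs = stats::runif(n_genes, 0.05, 0.5),
    causal_genes = sort(sample.int(n_genes, n_causal_genes)),
    bit_density = stats::runif(n_bits, 0.05, 0.4),
    causal_bits = sort(sample.int(n_bits, bits_per_gene * n_causal_genes)),
    gene_sign = sample(c(-1, 1), n_causal_genes, replace = TRUE),
    drug_offsets = stats::rnorm(n_drugs, 0, drug_offset_sd),
    cell_offsets = stats::rnorm(n_cells, 0, cell_offset_sd),
    desc_mean = stats::runif(n_descriptors, -1, 1),
    desc_sd = stats::runif(n_descriptors, 0.5, 1.5)
  )})
  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  # causal genes get mid-range mutation frequencies and causal bits
  # mid-range densities so the planted signal varies across the panel
  mutation_freqs <- rng$mutation_freqs
  mutation_freqs[rng$causal_genes] <-
    seq(0.25, 0.5, length.out = n_causal_genes)
  bit_density <- rng$bit_density
  bit_density[rng$causal_bits] <- 0.35
  # all of a gene's interaction coefficients share one sign: a mutation
  # either sensitizes or desensitizes cells to its chemotype, so the
  # gene keeps a visible marginal effect alongside the interaction
  effects <- data.frame(
    gene = rep(gene_ids[rng$causal_genes], each = bits_per_gene),
    bit = rng$causal_bits,
    gamma = effect_size * rep(rng$gene_sign, each = bits_per_gene),
    stringsAsFactors = FALSE
  )
  structure(list(
    n_cells = as.integer(n_cells), n_drugs = as.integer(n_drugs),
    n_genes = as.integer(n_genes),
    gene_ids = gene_ids,
    cell_line_ids = sprintf("cell_%04d", seq_len(n_cells)),
    drug_ids = sprintf("drug_%03d", seq_len(n_drugs)),
    mutation_freqs = stats::setNames(mutation_freqs, gene_ids),
    causal_genes = gene_ids[rng$causal_genes],
    causal_bits = rng$causal_bits,
    interaction_effects = effects,
    drug_offsets = stats::setNames(rng$drug_offsets, sprintf("drug_%03d", seq_len(n_drugs))),
    cell_offsets = stats::setNames(rng$cell_offsets, sprintf("cell_%04d", seq_len(n_cells))),
    baseline = baseline, noise_sd = noise_sd,
    n_descriptors = as.integer(n_descriptors), n_bits = as.integer(n_bits),
    bit_density = bit_density,
    desc_mean = rng$desc_mean, desc_sd = rng$desc_sd,
    missing_fraction = missing_fraction,
    clip_lo = clip_lo, clip_hi = clip_hi,
    seed = as.integer(seed)
  ), class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf(paste0(
    "ground_truth_model: %d cells x %d drugs x %d genes\n",
    "  %d causal genes x %d bits, |gamma| = %s, noise sd %.2f, baseline %.2f\n",
    "  missing fraction %.2f, seed %d\n"),
    x$n_cells, x$n_drugs, x$n_genes, length(x$causal_genes),
    nrow(x$interaction_effects) / max(1L, length(x$causal_genes)),
    format(unique(abs(x$interaction_effects$gamma))[1L]),
    x$noise_sd, x$baseline, x$missing_fraction, x$seed))
  invisible(x)
}

#' The desk-scale synthetic preset
#'
#' Convenience wrapper for the default [ground_truth_model()] with a
#' chosen seed: 300 cell lines x 40 drugs x 145 genes, 10 causal genes,
#' 12,000 records, noise sd 0.5.  Sized so full classification and
#' regression pipelines run in minutes on one CPU.
#'
#' The baseline is recentred with [plant_class_balance()] so the
#' expected active fraction at the 1 uM cutoff is 0.5: the primary
#' cutoff then sits in the balanced regime and the 0.1/10 uM cutoffs
#' produce moderate, realistic imbalance.
#'
#' @param seed master seed.
#' @param ... overrides passed to [ground_truth_model()].
#' @return a `ground_truth_model`.
#' @export
desk_preset <- function(seed = 1L, ...) {
  plant_class_balance(ground_truth_model(seed = seed, ...), 1e-6, 0.5)
}

#' The regression noise-floor benchmark preset
#'
#' A desk-scale variant designed so the planted signal is fully
#' recoverable in principle by a split-based learner: drug potency
#' offsets dominate, gene-by-chemistry interactions are small (effect
#' 0.1) and cell offsets nearly negligible (sd 0.15).  On this preset
#' the distance between the pooled out-of-fold regression RMSE and the
#' generative noise sd measures pipeline loss alone, not the model-class
#' bias a forest shows on dense interaction structure (see the methods
#' vignette).
#'
#' @param seed master seed.
#' @param ... overrides passed to [ground_truth_model()].
#' @return a `ground_truth_model` with noise sd 0.5.
#' @export
noise_floor_preset <- function(seed = 1L, ...) {
  plant_class_balance(
    ground_truth_model(effect_size = 0.1, cell_offset_sd = 0.15,
                       seed = seed, ...),
    1e-6, 0.5)
}

#' Generate a synthetic screening dataset from a ground-truth model
#'
#' Mutations are independent Bernoulli draws with the model's per-gene
#' frequencies; fingerprints are independent per-bit Bernoulli draws plus
#' Gaussian continuous descriptors; log10 IC50 follows the model's
#' interaction surface plus noise, clipped to the screening range; a
#' `missing_fraction` of records is flagged unobserved uniformly at
#' random.  Identical model (and seed) gives identical output.
#'
#' @param model a [ground_truth_model()].
#' @return list with `panel` ([oncogene_panel()]), `drugs`
#'   ([drug_library()]), `sens` ([sensitivity_table()]) and `model` (the
#'   ground truth, for recovery tests).
#' @export
generate_dataset <- function(model) {
  stopifnot(inherits(model, "ground_truth_model"))
  set.seed(derive_seed(model$seed, "generate"))
  n_c <- model$n_cells; n_d <- model$n_drugs; n_g <- model$n_genes
  mut <- matrix(stats::rbinom(n_c * n_g, 1L,
                              rep(model$mutation_freqs, each = n_c)),
                n_c, n_g, dimnames = list(model$cell_line_ids, model$gene_ids))
  panel <- oncogene_panel(mut)

  desc <- matrix(stats::rnorm(n_d * model$n_descriptors,
                              mean = rep(model$desc_mean, each = n_d),
                              sd = rep(model$desc_sd, each = n_d)),
                 n_d, model$n_descriptors)
  bits <- matrix(stats::rbinom(n_d * model$n_bits, 1L,
                               rep(model$bit_density, each = n_d)),
                 n_d, model$n_bits)
  fp <- cbind(desc, bits)
  colnames(fp) <- sprintf("fp_%04d", seq_len(ncol(fp)))
  drugs <- drug_library(model$drug_ids, fp, n_bits = model$n_bits)

  # interaction surface: rows cells, cols drugs
  eff <- model$interaction_effects
  inter <- matrix(0, n_c, n_d)
  for (i in seq_len(nrow(eff))) {
    g <- mut[, eff$gene[i]]                       # length n_c
    f <- bits[, eff$bit[i]]                       # length n_d
    inter <- inter + eff$gamma[i] * tcrossprod(g, f)
  }
  y <- model$baseline +
    matrix(model$cell_offsets, n_c, n_d) +
    matrix(model$drug_offsets, n_c, n_d, byrow = TRUE) +
    inter +
    matrix(stats::rnorm(n_c * n_d, 0, model$noise_sd), n_c, n_d)
  n_clip <- sum(y < model$clip_lo | y > model$clip_hi)
  if (n_clip > 0L) {
    message(sprintf("generate_dataset: clipped %d of %d log10 IC50 values to [%.2f, %.2f]",
                    n_clip, length(y), model$clip_lo, model$clip_hi))
  }
  y <- pmin(pmax(y, model$clip_lo), model$clip_hi)

  rec <- data.frame(
    drug_id = rep(model$drug_ids, each = n_c),
    cell_line_id = rep(model$cell_line_ids, times = n_d),
    log10_ic50 = as.vector(y),
    stringsAsFactors = FALSE
  )
  rec$observed <- TRUE
  if (model$missing_fraction > 0) {
    n_miss <- round(model$missing_fraction * nrow(rec))
    miss <- sample.int(nrow(rec), n_miss)
    rec$observed[miss] <- FALSE
    rec$log10_ic50[miss] <- NA_real_
  }
  list(panel = panel, drugs = drugs, sens = sensitivity_table(rec),
       model = model)
}

#' Write the ground-truth parameters as a JSON sidecar
#'
#' Records every planted parameter of the generative model so recovery
#' experiments can be scored without access to the R object.
#'
#' @param model a [ground_truth_model()].
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_ground_truth <- function(model, path) {
  stopifnot(inherits(model, "ground_truth_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# internal: Monte-Carlo draw of the record-level effect distribution
# (everything except the baseline), using the realized offsets.
sample_effect_distribution <- function(model, n = 200000L, seed_label = "balance") {
  set.seed(derive_seed(model$seed, seed_label))
  eff <- model$interaction_effects
  g_p <- model$mutation_freqs[eff$gene]
  f_p <- model$bit_density[eff$bit]
  s <- sample(model$cell_offsets, n, replace = TRUE) +
    sample(model$drug_offsets, n, replace = TRUE) +
    stats::rnorm(n, 0, model$noise_sd)
  # interactions share gene draws across bits of the same gene and, in
  # principle, bit draws across genes; replicate that dependence
  genes <- unique(eff$gene)
  mut_draw <- matrix(stats::rbinom(n * length(genes), 1L, rep(model$mutation_freqs[genes], each = n)),
                     n, length(genes), dimnames = list(NULL, genes))
  bits <- unique(eff$bit)
  bit_draw <- matrix(stats::rbinom(n * length(bits), 1L, rep(model$bit_density[bits], each = n)),
                     n, length(bits), dimnames = list(NULL, as.character(bits)))
  for (i in seq_len(nrow(eff))) {
    s <- s + eff$gamma[i] * mut_draw[, eff$gene[i]] * bit_draw[, as.character(eff$bit[i])]
  }
  s
}

#' Recenter the baseline to hit a target active fraction
#'
#' Adjusts the model's baseline `mu` so that the expected fraction of
#' records with IC50 at or below `cutoff_molar` equals
#' `target_active_fraction`, computed by Monte Carlo from the generative
#' distribution (realized offsets, planted interactions, noise).  Errors
#' if the target is unreachable given the clipping bounds.
#'
#' @param model a [ground_truth_model()].
#' @param cutoff_molar activity cutoff in molar (e.g. `1e-6` for 1 uM).
#' @param target_active_fraction desired expected active fraction,
#'   strictly inside (0, 1).
#' @param n_mc Monte-Carlo sample size.
#' @return the model with an adjusted `baseline`.
#' @export
plant_class_balance <- function(model, cutoff_molar, target_active_fraction,
                                n_mc = 200000L) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (target_active_fraction <= 0 || target_active_fraction >= 1) {
    of_error("target_active_fraction must lie strictly inside (0, 1)",
             "oncoforest_config_error")
  }
  if (cutoff_molar <= 0) of_error("cutoff must be positive molar",
                                  "oncoforest_config_error")
  cut_log <- log10(cutoff_molar)
  if (cut_log <= model$clip_lo || cut_log >= model$clip_hi) {
    of_error("activity cutoff lies outside the clipping bounds; target unreachable",
             "oncoforest_config_error")
  }
  s <- sample_effect_distribution(model, n_mc)
  mu <- cut_log - stats::quantile(s, target_active_fraction, names = FALSE,
                                  type = 8)
  y <- mu + s
  clipped <- mean(y < model$clip_lo | y > model$clip_hi)
  y <- pmin(pmax(y, model$clip_lo), model$clip_hi)
  achieved <- mean(y <= cut_log)
  if (clipped > 0.5 || abs(achieved - target_active_fraction) > 0.02) {
    of_error(sprintf(
      "target active fraction %.3f unreachable under clipping (achieved %.3f, %.0f%% clipped)",
      target_active_fraction, achieved, 100 * clipped),
      "oncoforest_config_error")
  }
  model$baseline <- mu
  model
}
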