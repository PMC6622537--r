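# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small panel for fast unit tests: 80 cells x 12 drugs x 30 genes
small_model <- function(seed = 11L, ...) {
  ground_truth_model(n_cells = 80L, n_drugs = 12L, n_genes = 30L,
                     n_causal_genes = 4L, seed = seed, ...)
}

small_dataset <- function() {
  cached("small", suppressMessages(generate_dataset(
    plant_class_balance(small_model(), 1e-6, 0.5))))
}

# a mid-sized panel for the heavier property checks:
# 150 cells x 30 drugs x 60 genes, 10 causal genes
mid_model <- function(seed = 21L, ...) {
  ground_truth_model(n_cells = 150L, n_drugs = 30L, n_genes = 60L,
                     n_causal_genes = 10L, seed = seed, ...)
}

mid_dataset <- function() {
  cached("mid", suppressMessages(generate_dataset(
    plant_class_balance(mid_model(), 1e-6, 0.5))))
}

# the desk-scale preset used by the validation-protocol checks
desk_dataset <- function() {
  cached("desk", suppressMessages(generate_dataset(desk_preset(seed = 1L))))
}

# random valid confusion counts for metric identity checks
random_confusion <- function(rng_n = 1000L, seed = 5L) {
  set.seed(seed)
  data.frame(tp = sample(0:200, rng_n, TRUE), tn = sample(0:200, rng_n, TRUE),
             fp = sample(0:200, rng_n, TRUE), fn = sample(0:200, rng_n, TRUE))
}

# expand confusion counts into prediction/truth label vectors
labels_from_counts <- function(tp, tn, fp, fn) {
  list(pred = rep(c("active", "inactive", "active", "inactive"),
                  c(tp, tn, fp, fn)),
       truth = rep(c("active", "inactive", "inactive", "active"),
                   c(tp, tn, fp, fn)))
}

has_chemistry <- function() {
  requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
}
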