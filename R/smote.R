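#' SMOTE class balancing
#'
#' When the minority class falls below `minority_threshold` of the rows,
#' rebalances the matrix by (i) synthesising minority rows as convex
#' combinations `x + u (x' - x)`, `u ~ Uniform(0, 1)`, of a random
#' minority row `x` and one of its `k_neighbors` minority-class nearest
#' neighbours `x'` (Euclidean), and (ii) randomly under-sampling the
#' majority class; both classes end at half the original row count, so
#' the output class ratio is 1.  A matrix whose minority fraction is
#' already at or above the threshold is returned unchanged.
#'
#' @param fm classify-mode [assemble_matrix()] result with both classes.
#' @param minority_threshold apply-balancing threshold on the minority
#'   fraction (default 0.20).
#' @param k_neighbors minority nearest neighbours sampled from
#'   (default 5); silently lowered to `minority count - 1` with a
#'   warning when the minority class is smaller.
#' @param seed integer seed.
#' @return a balanced `feature_matrix`; synthetic rows carry
#'   `drug_id`/`cell_line_id` `"synthetic"`.  Attribute `n_synthetic`
#'   records how many rows were synthesised (0 when returned unchanged).
#' @export
smote_balance <- function(fm, minority_threshold = 0.20, k_neighbors = 5L,
                          seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), fm$mode == "classify")
  tab <- table(fm$label)
  if (any(tab == 0L)) of_error("both classes must be present",
                               "oncoforest_degenerate_error")
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  min_frac <- min(tab) / sum(tab)
  if (min_frac >= minority_threshold) {
    attr(fm, "n_synthetic") <- 0L
    return(fm)
  }
  n_min <- as.integer(min(tab))
  if (n_min < 2L) of_error("minority class has fewer than 2 rows",
                           "oncoforest_degenerate_error")
  k <- as.integer(k_neighbors)
  if (n_min <= k) {
    k <- n_min - 1L
    warning(sprintf("minority count %d <= k_neighbors; falling back to k = %d",
                    n_min, k), call. = FALSE)
  }
  set.seed(derive_seed(seed, "smote"))
  target <- max(1L, round(nrow(fm$features) / 2))
  min_idx <- which(fm$label == minority)
  maj_idx <- which(fm$label == majority)
  X_min <- fm$features[min_idx, , drop = FALSE]
  # k+1 because each point is its own nearest neighbour
  nn <- nearest_neighbours(X_min, X_min, k + 1L)[, -1L, drop = FALSE]
  n_syn <- max(0L, target - n_min)
  base <- sample.int(n_min, n_syn, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
  u <- stats::runif(n_syn)
  syn <- X_min[base, , drop = FALSE] +
    u * (X_min[pick, , drop = FALSE] - X_min[base, , drop = FALSE])
  keep_maj <- sample(maj_idx, min(length(maj_idx), target))
  out <- fm
  out$features <- rbind(fm$features[min_idx, , drop = FALSE], syn,
                        fm$features[keep_maj, , drop = FALSE])
  rownames(out$features) <- NULL
  out$drug_id <- c(fm$drug_id[min_idx], rep("synthetic", n_syn),
                   fm$drug_id[keep_maj])
  out$cell_line_id <- c(fm$cell_line_id[min_idx], rep("synthetic", n_syn),
                        fm$cell_line_id[keep_maj])
  out$label <- factor(c(rep(minority, n_min + n_syn),
                        rep(majority, length(keep_maj))),
                      levels = levels(fm$label))
  attr(out, "n_synthetic") <- n_syn
  out
}
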