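#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic step in the package draws its own seed from the master
#' seed plus a purpose label, via a small deterministic string hash
#' (FNV-1a, folded into the positive 32-bit integer range).  Adding a new
#' experiment therefore never perturbs the randomness of an existing one.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the consumer
#'   (e.g. `"kfold"`, fold number, repeat number).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "kfold", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(key)
  # FNV-1a in double arithmetic; all intermediates stay < 2^53 so exact
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2147483629
  }
  # diffusion finalizer: without it, keys differing in one trailing
  # character give seeds offset by ~the FNV prime, and RNG streams from
  # arithmetically related seeds can correlate
  h <- h %% 2147483646 + 1
  for (r in 1:3) {
    h <- (h * 48271) %% 2147483647            # exact: < 2^53
    h <- bitwXor(as.integer(h), as.integer(h %/% 65536))
    h <- h %% 2147483646 + 1
  }
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an IC50 cutoff in micromolar to log10 molar units
#'
#' Activity cutoffs are quoted in micromolar throughout (the screening
#' convention); labels are computed on the log10 molar scale, so the
#' conversion is `log10(um) - 6`.
#'
#' @param um cutoff(s) in micromolar, strictly positive.
#' @return log10 of the molar concentration.
#' @export
#' @examples
#' cutoff_um_to_log10m(1)   # -6
cutoff_um_to_log10m <- function(um) {
  if (any(!is.finite(um)) || any(um <= 0)) {
    stop("IC50 cutoffs must be finite and strictly positive (micromolar)")
  }
  log10(um) - 6
}

#' The activity-cutoff grid used for the ROC sweep
#'
#' The full sweep grid in micromolar: 44 cutoffs spanning 0.01 uM to
#' 5000 uM, plus the primary 1 uM screening cutoff (45 values).
#'
#' @return sorted numeric vector of cutoffs in micromolar.
#' @export
default_cutoff_grid_um <- function() {
  sort(unique(c(
    0.01, 0.05, 0.08, 0.1, 0.5, 0.6, 0.7, 0.8, 1,
    2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20,
    30, 40, 50, 75, 100, 150, 200, 250, 300, 350, 400, 450, 500,
    600, 700, 800, 900, 1000, 2500, 3000, 4000, 5000
  )))
}

# internal: stop() with a class so tests can assert on error types
of_error <- function(msg, class) {
  stop(structure(
    class = c(class, "oncoforest_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: exact k nearest neighbours by squared Euclidean distance,
# computed blockwise with crossprod so large queries stay in BLAS.
# Returns an n_query x k matrix of row indices into `train`.
nearest_neighbours <- function(train, query, k, block = 2000L) {
  train <- as.matrix(train); query <- as.matrix(query)
  stopifnot(ncol(train) == ncol(query), k >= 1L, k <= nrow(train))
  tn2 <- rowSums(train^2)
  out <- matrix(NA_integer_, nrow(query), k)
  i <- 1L
  while (i <= nrow(query)) {
    j <- min(i + block - 1L, nrow(query))
    q <- query[i:j, , drop = FALSE]
    d2 <- outer(rowSums(q^2), tn2, "+") - 2 * tcrossprod(q, train)
    # tiny negative values can appear from rounding
    d2[d2 < 0] <- 0
    idx <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
    out[i:j, ] <- idx
    i <- j + 1L
  }
  out
}
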