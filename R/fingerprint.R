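# Chemical descriptor fingerprints: 192 two-dimensional descriptors
# followed by a 1024-bit circular fingerprint of radius 3 (ECFP6
# equivalent).  Descriptors are computed from the 2-D molecular graph
# (ChemmineR/ChemmineOB parse the SMILES); the manifest of descriptor
# names is fixed by descriptor_manifest().  Exact numeric identity with
# any other toolkit's descriptor set is not a goal: models depend on
# descriptor informativeness, not identity.

ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se")
ELEMENT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                     Br = 1, I = 1, B = 3, Si = 4, Se = 2, H = 1)
ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904,
                  B = 10.81, Si = 28.085, Se = 78.971)
ELEMENT_EN <- c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, P = 2.19, F = 3.98,
                Cl = 3.16, Br = 2.96, I = 2.66, B = 2.04, Si = 1.90,
                Se = 2.55)
ELEMENT_RCOV <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                  F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84,
                  Si = 1.11, Se = 1.20)

# internal: parse a SMILES string into a 2-D molecular graph
parse_molecule <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    of_error("ChemmineR/ChemmineOB are required for SMILES parsing",
             "oncoforest_chemistry_error")
  }
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0L ||
      nrow(ChemmineR::atomblock(sdf[[1]])) == 0L) {
    of_error(sprintf("cannot parse SMILES '%s'", smiles),
             "oncoforest_chemistry_error")
  }
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  elements <- gsub("_[0-9]+$", "", rownames(ab))
  n <- length(elements)
  bb <- ChemmineR::bondblock(mol)
  bonds <- if (is.null(bb) || NROW(bb) == 0L || NCOL(bb) < 3L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  }
  # drop explicit hydrogens into implicit counts
  is_h <- elements == "H"
  explicit_h <- integer(n)
  if (any(is_h)) {
    for (k in seq_len(nrow(bonds))) {
      if (is_h[bonds$a1[k]]) explicit_h[bonds$a2[k]] <- explicit_h[bonds$a2[k]] + 1L
      if (is_h[bonds$a2[k]]) explicit_h[bonds$a1[k]] <- explicit_h[bonds$a1[k]] + 1L
    }
    keep <- which(!is_h)
    remap <- match(seq_len(n), keep)
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    elements <- elements[keep]; explicit_h <- explicit_h[keep]
    n <- length(elements)
  }
  deg <- integer(n); bond_sum <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    for (a in c(bonds$a1[k], bonds$a2[k])) deg[a] <- deg[a] + 1L
    bond_sum[bonds$a1[k]] <- bond_sum[bonds$a1[k]] + bonds$order[k]
    bond_sum[bonds$a2[k]] <- bond_sum[bonds$a2[k]] + bonds$order[k]
  }
  val <- ELEMENT_VALENCE[elements]
  val[is.na(val)] <- 4
  n_h <- pmax(0L, as.integer(val) - bond_sum - explicit_h) + explicit_h
  # adjacency list
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
  }
  list(smiles = smiles, sdf = sdf, elements = elements, bonds = bonds,
       degree = deg, n_h = n_h, adj = adj, n = n)
}

# internal: all-pairs topological distances by BFS (small molecules)
topo_distances <- function(mol) {
  n <- mol$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier) > 0L) {
      d <- d + 1
      nxt <- unique(unlist(mol$adj[frontier]))
      nxt <- nxt[D[s, nxt] > d]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# internal: bond-in-ring flags (a bond is in a ring iff it is not a
# bridge); bridges found by connectivity check without the bond
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  in_ring <- logical(nb)
  for (k in seq_len(nb)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    # BFS from a to b avoiding bond k
    seen <- logical(mol$n); seen[a] <- TRUE
    frontier <- a
    while (length(frontier) > 0L && !seen[b]) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in mol$adj[[v]]) {
          if ((v == a && w == b) || (v == b && w == a)) {
            # skip only the k-th bond itself, not parallel paths
            if (identical(sort(c(v, w)), sort(c(a, b)))) next
          }
          if (!seen[w]) { seen[w] <- TRUE; nxt <- c(nxt, w) }
        }
      }
      frontier <- nxt
    }
    in_ring[k] <- seen[b]
  }
  in_ring
}

# internal: 32-bit FNV-1a over a string, exact in double arithmetic
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2147483629
  }
  h
}

# internal: circular fingerprint, radius 3, folded to n_bits
circular_fingerprint <- function(mol, radius = 3L, n_bits = 1024L) {
  inv <- vapply(seq_len(mol$n), function(i) {
    fnv1a(paste(mol$elements[i], mol$degree[i], mol$n_h[i], sep = "|"))
  }, numeric(1L))
  bond_order <- matrix(0L, mol$n, mol$n)
  for (k in seq_len(nrow(mol$bonds))) {
    bond_order[mol$bonds$a1[k], mol$bonds$a2[k]] <- mol$bonds$order[k]
    bond_order[mol$bonds$a2[k], mol$bonds$a1[k]] <- mol$bonds$order[k]
  }
  bits <- numeric(0)
  bits <- c(bits, inv)
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- vapply(seq_len(mol$n), function(i) {
      nb <- mol$adj[[i]]
      env <- if (length(nb) == 0L) "" else {
        paste(sort(paste0(bond_order[i, nb], ":",
                          format(cur[nb], scientific = FALSE))),
              collapse = ",")
      }
      fnv1a(paste(r, format(cur[i], scientific = FALSE), env, sep = "|"))
    }, numeric(1L))
    bits <- c(bits, nxt)
    cur <- nxt
  }
  out <- numeric(n_bits)
  out[(bits %% n_bits) + 1] <- 1
  out
}

#' Manifest of the 192 two-dimensional chemical descriptors
#'
#' The fixed, documented list of the continuous descriptor block:
#' OpenBabel bulk properties, element counts, constitutional and
#' topological indices, ring statistics, Moreau-Broto and centered
#' autocorrelations over atomic properties, and the topological
#' distance-pair distribution.
#'
#' @return data.frame with columns `position` (1..192), `name`,
#'   `family`.
#' @export
descriptor_manifest <- function() {
  props <- c("mass", "electroneg", "cov_radius", "n_h", "degree", "in_ring")
  fam <- list(
    openbabel = c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF"),
    element_count = paste0("n_", ELEMENTS),
    constitutional = c("n_heavy", "n_bonds", "n_implicit_h", "n_rings_cyclomatic",
                       "n_single_bonds", "n_double_bonds", "n_triple_bonds",
                       "n_rotatable_bonds", "max_degree", "mean_degree",
                       "n_degree_1", "n_degree_2", "n_degree_3", "n_degree_4"),
    topological = c("wiener_index", "harary_index", "zagreb_m1", "zagreb_m2",
                    "randic_chi0", "randic_chi1", "graph_diameter",
                    "graph_radius", "mean_topo_distance"),
    ring = c("n_ring_atoms", "n_ring_bonds", "ring_atom_fraction",
             "n_ring_systems", "max_ring_system_size", "mean_ring_system_size"),
    ats = as.vector(outer(props, 1:10, function(p, d) paste0("ats_", p, "_d", d))),
    centered_ac = as.vector(outer(props, 1:8, function(p, d) paste0("cac_", p, "_d", d))),
    dist_count = paste0("n_pairs_d", 1:35)
  )
  out <- data.frame(
    position = seq_len(sum(lengths(fam))),
    name = unlist(fam, use.names = FALSE),
    family = rep(names(fam), lengths(fam)),
    stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 192L)
  out
}

# internal: the 192 continuous descriptors for a parsed molecule
continuous_descriptors <- function(mol) {
  n <- mol$n
  D <- topo_distances(mol)
  finD <- D[is.finite(D) & D > 0]
  rb <- ring_bonds(mol)
  ring_atom <- rep(FALSE, n)
  if (any(rb)) {
    ring_atom[unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb]))] <- TRUE
  }
  deg <- mol$degree

  ob <- tryCatch({
    p <- ChemmineR::propOB(mol$sdf)
    unlist(p[1L, c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")])
  }, error = function(e) NULL)
  if (is.null(ob) || length(ob) != 8L) {
    # property backend unavailable for this input: fall back to graph MW
    ob <- c(MW = sum(ELEMENT_MASS[mol$elements], na.rm = TRUE) +
              1.008 * sum(mol$n_h),
            logP = 0, TPSA = 0, MR = 0, HBA1 = 0, HBA2 = 0, HBD = 0, nF = 0)
  }

  elem_counts <- vapply(ELEMENTS, function(e) sum(mol$elements == e),
                        numeric(1L))

  nb <- nrow(mol$bonds)
  n_rings <- nb - n + length(unique(components_of(mol)))
  rotatable <- sum(!rb & mol$bonds$order == 1L &
                     deg[mol$bonds$a1] > 1L & deg[mol$bonds$a2] > 1L)
  constitutional <- c(
    n, nb, sum(mol$n_h), n_rings,
    sum(mol$bonds$order == 1L), sum(mol$bonds$order == 2L),
    sum(mol$bonds$order == 3L), rotatable,
    if (n > 0) max(deg) else 0, mean(deg),
    sum(deg == 1L), sum(deg == 2L), sum(deg == 3L), sum(deg == 4L))

  pairs_d <- function(d) sum(D[upper.tri(D)] == d)
  chi0 <- sum(1 / sqrt(deg[deg > 0]))
  chi1 <- if (nb > 0) sum(1 / sqrt(deg[mol$bonds$a1] * deg[mol$bonds$a2])) else 0
  ecc <- if (n > 1) apply(ifelse(is.finite(D), D, NA), 1L, max, na.rm = TRUE) else 0
  topological <- c(
    sum(finD) / 2, sum(1 / finD) / 2,
    sum(deg^2), if (nb > 0) sum(deg[mol$bonds$a1] * deg[mol$bonds$a2]) else 0,
    chi0, chi1,
    if (length(finD)) max(ecc) else 0, if (length(finD)) min(ecc) else 0,
    if (length(finD)) mean(finD) else 0)

  comp <- ring_systems(mol, rb)
  ring_stats <- c(sum(ring_atom), sum(rb),
                  if (n > 0) mean(ring_atom) else 0,
                  length(comp),
                  if (length(comp)) max(lengths(comp)) else 0,
                  if (length(comp)) mean(lengths(comp)) else 0)

  prop_vals <- cbind(
    mass = unname(ELEMENT_MASS[mol$elements]),
    electroneg = unname(ELEMENT_EN[mol$elements]),
    cov_radius = unname(ELEMENT_RCOV[mol$elements]),
    n_h = mol$n_h, degree = deg, in_ring = as.numeric(ring_atom))
  prop_vals[is.na(prop_vals)] <- 0
  ats <- as.vector(vapply(1:10, function(d) {
    sel <- is.finite(D) & D == d
    vapply(seq_len(ncol(prop_vals)), function(j) {
      x <- prop_vals[, j]
      sum(outer(x, x)[sel]) / 2
    }, numeric(1L))
  }, numeric(ncol(prop_vals))))
  cac <- as.vector(vapply(1:8, function(d) {
    sel <- is.finite(D) & D == d
    m <- sum(sel) / 2
    vapply(seq_len(ncol(prop_vals)), function(j) {
      if (m == 0) return(0)
      x <- prop_vals[, j] - mean(prop_vals[, j])
      sum(outer(x, x)[sel]) / (2 * m)
    }, numeric(1L))
  }, numeric(ncol(prop_vals))))
  dist_counts <- vapply(1:35, pairs_d, numeric(1L))

  out <- c(unname(ob), elem_counts, constitutional, topological, ring_stats,
           ats, cac, dist_counts)
  stopifnot(length(out) == 192L, all(is.finite(out)))
  out
}

# internal: connected components of the heavy-atom graph
components_of <- function(mol) {
  comp <- integer(mol$n); cur <- 0L
  for (s in seq_len(mol$n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s; comp[s] <- cur
    while (length(frontier) > 0L) {
      nxt <- unlist(mol$adj[frontier])
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- unique(nxt)
    }
  }
  split(seq_len(mol$n), comp)
}

# internal: connected components of the ring subgraph
ring_systems <- function(mol, rb) {
  if (!any(rb)) return(list())
  atoms <- sort(unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb])))
  adj <- lapply(atoms, function(a) {
    nb <- c(mol$bonds$a2[rb & mol$bonds$a1 == a],
            mol$bonds$a1[rb & mol$bonds$a2 == a])
    match(nb, atoms)
  })
  comp <- integer(length(atoms)); cur <- 0L
  for (s in seq_along(atoms)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L; frontier <- s; comp[s] <- cur
    while (length(frontier) > 0L) {
      nxt <- unlist(adj[frontier])
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- unique(nxt)
    }
  }
  split(atoms, comp)
}

#' Compute the 1216-element chemical fingerprint of a molecule
#'
#' Concatenates the 192 continuous 2-D descriptors (see
#' [descriptor_manifest()]) with a radius-3 circular fingerprint folded
#' to 1024 bits.  Deterministic for a given SMILES.
#'
#' @param smiles a single SMILES string.
#' @param n_bits circular fingerprint length (default 1024).
#' @return named numeric vector of length `192 + n_bits` with names
#'   `fp_0001 ...`.
#' @export
#' @examplesIf requireNamespace("ChemmineR", quietly = TRUE) && requireNamespace("ChemmineOB", quietly = TRUE)
#' fp <- compute_fingerprint("c1ccccc1")
#' sum(fp[193:1216])   # bits set for benzene
compute_fingerprint <- function(smiles, n_bits = 1024L) {
  mol <- parse_molecule(smiles)
  out <- c(continuous_descriptors(mol),
           circular_fingerprint(mol, radius = 3L, n_bits = n_bits))
  names(out) <- sprintf("fp_%04d", seq_along(out))
  out
}

#' Build a drug library from SMILES strings
#'
#' @param drug_ids identifiers, one per SMILES.
#' @param smiles SMILES strings.
#' @param n_bits circular fingerprint length.
#' @return a [drug_library()] with computed fingerprints.
#' @export
fingerprint_library <- function(drug_ids, smiles, n_bits = 1024L) {
  stopifnot(length(drug_ids) == length(smiles))
  fp <- t(vapply(smiles, compute_fingerprint, numeric(192L + n_bits),
                 n_bits = n_bits))
  rownames(fp) <- drug_ids
  drug_library(drug_ids, fp, smiles = smiles, n_bits = n_bits)
}

#' Bundled example SMILES structures
#'
#' A small library of 20 well-known anticancer and kinase-inhibitor
#' structures, bundled to exercise the fingerprint pipeline end-to-end
#' (the synthetic generator does not produce SMILES).
#'
#' @return data.frame with `drug_id` and `smiles`.
#' @export
example_smiles <- function() {
  path <- system.file("extdata", "example_drugs.csv", package = "oncoforest",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
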