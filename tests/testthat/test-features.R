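test_that("mutation entropy matches the binary-entropy formula", {
  mk <- function(p, n = 1000L) {
    m <- matrix(0L, n, 1, dimnames = list(sprintf("c%d", 1:n), "g"))
    m[seq_len(round(p * n)), 1] <- 1L
    oncogene_panel(m)
  }
  expect_equal(unname(mutation_entropy(mk(0.5))), 1.0)
  expect_equal(unname(mutation_entropy(mk(0))), 0.0)
  expect_equal(unname(mutation_entropy(mk(1))), 0.0)
  # direct evaluation of -p log2 p - (1-p) log2(1-p) at p = 0.1
  expect_equal(unname(mutation_entropy(mk(0.1))), 0.4690, tolerance = 1e-4)
  # symmetry H(p) = H(1-p)
  expect_equal(mutation_entropy(mk(0.3)), mutation_entropy(mk(0.7)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(mutation_entropy(oncogene_panel(
    matrix(integer(0), 2, 0), cell_line_ids = c("c1", "c2"),
    gene_ids = character(0))),
    class = "oncoforest_empty_error")
})

test_that("entropy gene selection equals the |p - 0.5| brute-force order", {
  set.seed(31)
  n_cells <- 200L
  p <- runif(145, 0.01, 0.99)
  m <- matrix(rbinom(n_cells * 145, 1, rep(p, each = n_cells)), n_cells, 145,
              dimnames = list(sprintf("c%d", 1:n_cells), sprintf("g%03d", 1:145)))
  panel <- oncogene_panel(m)
  sel <- select_top_entropy_genes(panel, 145L)
  # brute-force oracle: the gene whose mutated and unmutated cell-line
  # counts are closest is most entropic, so the order is the integer
  # imbalance |2*count - n| ascending, ties by gene id
  imbalance <- abs(2L * colSums(m) - n_cells)
  oracle <- colnames(m)[order(imbalance, colnames(m))]
  expect_identical(sel, oracle)

  # dominance: the gene closest to 0.5 wins at k = 1
  m3 <- sapply(c(0.5, 0.9, 0.99), function(q) rbinom(500, 1, q))
  colnames(m3) <- c("mid", "high", "extreme")
  rownames(m3) <- sprintf("c%d", 1:500)
  expect_identical(select_top_entropy_genes(oncogene_panel(m3), 1L), "mid")
  expect_error(select_top_entropy_genes(panel, 0L),
               class = "oncoforest_config_error")
  expect_error(select_top_entropy_genes(panel, 146L),
               class = "oncoforest_config_error")
})

test_that("assembled matrices have the documented layout and labels", {
  d <- small_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  expect_identical(nrow(fm$features), nrow(d$sens))
  expect_identical(ncol(fm$features), 30L + 1216L)
  expect_identical(colnames(fm$features)[1:30], colnames(d$panel$mutation))
  # gene block is binary, chemistry block copied from the drug library
  expect_true(all(fm$features[, 1:30] %in% c(0, 1)))
  i <- 17L
  expect_equal(unname(fm$features[i, -(1:30)]),
               unname(d$drugs$fingerprints[d$sens$drug_id[i], ]))

  # inclusive boundary: log10 IC50 == cutoff is active
  sens <- sensitivity_table(data.frame(
    drug_id = d$drugs$drug_ids[1], cell_line_id = rownames(d$panel$mutation)[1:3],
    log10_ic50 = c(-6, -5.999, -6.001)))
  fm2 <- assemble_matrix(d$panel, d$drugs, sens,
                         labeling = labeling_config(1e-6))
  expect_identical(as.character(fm2$label), c("active", "inactive", "active"))

  # regress mode carries the raw target
  fr <- assemble_matrix(d$panel, d$drugs, d$sens, mode = "regress")
  expect_identical(fr$target, d$sens$log10_ic50)
})

test_that("full-size assembly yields the canonical 1361-feature rows", {
  # 145 gene bits + 1216 chemical descriptors
  d <- desk_dataset()
  fm <- assemble_matrix(d$panel, d$drugs, d$sens)
  expect_identical(ncol(fm$features), 1361L)
})

test_that("labeling is monotone in the cutoff and subsetting leaves chemistry intact", {
  d <- small_dataset()
  lab1 <- assemble_matrix(d$panel, d$drugs, d$sens,
                          labeling = labeling_config(1e-7))$label
  lab2 <- assemble_matrix(d$panel, d$drugs, d$sens,
                          labeling = labeling_config(1e-5))$label
  # raising the cutoff never turns an active row inactive
  expect_true(all(!(lab1 == "active" & lab2 == "inactive")))

  full <- assemble_matrix(d$panel, d$drugs, d$sens)
  sub <- assemble_matrix(d$panel, d$drugs, d$sens,
                         gene_subset = colnames(d$panel$mutation)[1:5])
  chem <- setdiff(colnames(full$features), colnames(d$panel$mutation))
  expect_identical(sub$features[, chem], full$features[, chem])
  expect_identical(ncol(sub$features), 5L + 1216L)
})

test_that("cartesian small cases give one row per observed pair", {
  mut <- matrix(c(0L, 1L, 0L, 1L, 1L, 0L), 3, 2,
                dimnames = list(c("c1", "c2", "c3"), c("g1", "g2")))
  fp <- matrix(c(0.5, -1.2, 0.3, 1.8, 1, 0, 1, 1), 2, 4,
               dimnames = list(NULL, sprintf("fp_%04d", 1:4)))
  drugs <- drug_library(c("d1", "d2"), fp, n_bits = 2L)
  sens <- sensitivity_table(expand.grid(
    drug_id = c("d1", "d2"), cell_line_id = c("c1", "c2", "c3"),
    stringsAsFactors = FALSE) |> transform(log10_ic50 = -6))
  fm <- assemble_matrix(oncogene_panel(mut), drugs, sens)
  expect_identical(nrow(fm$features), 6L)
})
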