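test_that("gene filter drops genes detected in too few nuclei", {
  # detection counts per gene: 0,1,2,3,4 over 4 cells
  counts <- rbind(c(0, 1, 1, 1, 1),
                  c(0, 0, 1, 1, 1),
                  c(0, 0, 0, 1, 1),
                  c(0, 0, 0, 0, 1))
  m <- toy_matrix(counts)
  expect_equal(ncol(gene_filter(m, 3)$counts), 2L)           # genes seen >= 3x
  expect_equal(gene_filter(m, 3)$gene_ids, c("G004", "G005"))
  expect_equal(ncol(gene_filter(m, 0)$counts), 5L)           # identity
  # a gene detected in only 2 cells is removed at the default threshold
  expect_false("G003" %in% gene_filter(m, 3)$gene_ids)
})

test_that("cell filter keeps nuclei with at least min_genes expressed (inclusive)", {
  set.seed(1)
  counts <- matrix(0, 3, 400)
  counts[1, 1:299] <- 1   # 299 genes -> removed at 300
  counts[2, 1:300] <- 1   # exactly 300 -> retained
  counts[3, 1:350] <- 1
  m <- toy_matrix(counts)
  kept <- cell_gene_count_filter(m, 300)
  expect_equal(kept$barcodes, c("B002", "B003"))
  expect_equal(nrow(cell_gene_count_filter(m, 0)$counts), 3L)
})

test_that("mito_fraction matches dense brute force and handles edge cases", {
  counts <- rbind(c(2, 90, 8), c(0, 50, 50), c(0, 0, 0))
  m <- toy_matrix(counts, symbols = c("MT-ND1", "ACTB", "GFAP"))
  frac <- mito_fraction(m)
  expect_equal(frac, c(2 / 100, 0, 0))

  set.seed(5)
  counts <- matrix(rpois(20 * 30, 1), 20, 30)
  syms <- sprintf("S%02d", 1:30); syms[c(3, 17)] <- c("MT-A", "mt-b")
  m <- toy_matrix(counts, symbols = syms)
  dense <- rowSums(counts[, c(3, 17)]) / rowSums(counts)
  dense[rowSums(counts) == 0] <- 0
  expect_equal(mito_fraction(m), dense, tolerance = 1e-12)

  m_none <- toy_matrix(counts)
  expect_warning(f0 <- mito_fraction(m_none), "prefix")
  expect_equal(f0, rep(0, 20))
})

test_that("outlier threshold equals Q(q) + k * IQR under the pinned convention", {
  totals <- c(100, 200, 300, 400, 1000)
  thr <- transcript_outlier_threshold(totals, 0.75, 1.5)
  ref <- unname(quantile(totals, 0.75, type = 7) +
                  1.5 * diff(quantile(totals, c(0.25, 0.75), type = 7)))
  expect_equal(thr, ref)
  expect_equal(sum(totals > thr), 1L)  # flags only the 1000-count cell

  # degenerate spread: IQR 0, nothing strictly exceeds the common value
  expect_equal(transcript_outlier_threshold(rep(7, 10)), 7)
  # k = 0 reduces to the anchoring quantile
  expect_equal(transcript_outlier_threshold(totals, 0.75, 0),
               unname(quantile(totals, 0.75, type = 7)))
})

test_that("apply_qc removes exactly the planted bad cells with per-rule attribution", {
  set.seed(8)
  ng <- 60
  base <- matrix(rpois(10 * ng, 3), 10, ng)     # 10 healthy cells
  base[base == 0] <- 1                          # all cells express all genes
  high_mito <- rpois(ng, 3) + 1; high_mito[1] <- 60        # gene 1 is MT-
  low_complex <- c(5, 2, rep(0, ng - 2))                   # 2 genes expressed
  doublet <- rpois(ng, 40) + 1                             # huge totals
  counts <- rbind(base, high_mito, low_complex, doublet)
  syms <- sprintf("S%02d", seq_len(ng)); syms[1] <- "MT-X"
  m <- toy_matrix(counts, symbols = syms)
  t <- qc_thresholds(min_cells_per_gene = 3, min_genes_per_cell = 10,
                     max_mito_fraction = 0.05)
  res <- apply_qc(m, t)

  expect_equal(res$report$cells_removed_min_genes, 1L)
  expect_equal(res$report$cells_removed_mito, 1L)
  expect_equal(res$report$cells_removed_outlier, 1L)
  expect_equal(res$matrix$barcodes, sprintf("B%03d", 1:10))

  # brute-force check of the survivor set
  keep_gene <- colSums(counts > 0) >= 3
  cmat <- counts[, keep_gene, drop = FALSE]
  keep1 <- rowSums(cmat > 0) >= 10
  cmat2 <- cmat[keep1, , drop = FALSE]
  frac <- rowSums(cmat2[, syms[keep_gene] == "MT-X", drop = FALSE]) / rowSums(cmat2)
  thr <- quantile(rowSums(cmat2), 0.75, type = 7) +
    1.5 * diff(quantile(rowSums(cmat2), c(0.25, 0.75), type = 7))
  survivors <- which(keep1)[!(frac > 0.05 | rowSums(cmat2) > thr)]
  expect_equal(res$matrix$barcodes, sprintf("B%03d", survivors))

  # attribution sums to total removed
  expect_equal(res$report$n_cells_in - res$report$n_cells_out,
               res$report$cells_removed_min_genes +
                 res$report$cells_removed_mito +
                 res$report$cells_removed_outlier)
})

test_that("permissive thresholds are the identity and QC is monotone", {
  set.seed(9)
  counts <- matrix(rpois(30 * 50, 2), 30, 50)
  syms <- sprintf("S%02d", 1:50); syms[1] <- "MT-1"
  m <- toy_matrix(counts, symbols = syms)
  res <- apply_qc(m, qc_thresholds(min_cells_per_gene = 0, min_genes_per_cell = 0,
                                   max_mito_fraction = 1, outlier_iqr_mult = 1e9))
  expect_equal(dim(res$matrix), dim(m))

  # raising min_genes_per_cell never increases the retained cell count;
  # raising the IQR multiplier never decreases it
  kept_cells <- function(t) nrow(apply_qc(m, t)$matrix$counts)
  n_by_min_genes <- vapply(c(0, 10, 20, 30, 40), function(g) {
    kept_cells(qc_thresholds(min_cells_per_gene = 3, min_genes_per_cell = g))
  }, integer(1))
  expect_true(all(diff(n_by_min_genes) <= 0))
  n_by_k <- vapply(c(0, 0.5, 1.5, 3, 100), function(k) {
    kept_cells(qc_thresholds(min_genes_per_cell = 0, outlier_iqr_mult = k))
  }, integer(1))
  expect_true(all(diff(n_by_k) >= 0))
})

test_that("a second QC pass with a huge IQR multiplier removes no further cells", {
  sim <- simulate_dataset(small_sim())
  t <- qc_thresholds(min_genes_per_cell = 80, outlier_iqr_mult = 1e9)
  one <- apply_qc(sim$samples[[1]], t)
  two <- apply_qc(one$matrix, t)
  # cells are idempotent; the gene filter may drop a few more genes since
  # detection counts are re-evaluated on the reduced cell set
  expect_equal(two$matrix$barcodes, one$matrix$barcodes)
  expect_true(all(two$matrix$gene_ids %in% one$matrix$gene_ids))
  # rerunning on an unchanged cell set is then fully idempotent
  three <- apply_qc(two$matrix, t)
  expect_equal(three$matrix$gene_ids, two$matrix$gene_ids)
})

test_that("all-cells-removed is a warning in the report, not an exception", {
  m <- toy_matrix(matrix(1, 2, 5))
  res <- apply_qc(m, qc_thresholds(min_cells_per_gene = 0,
                                   min_genes_per_cell = 100))
  expect_equal(res$report$n_cells_out, 0L)
  expect_equal(res$report$warning, "all cells removed")
})
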