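# Cell-detection-rate (CDR) statistics. The UMI matrix is binarized
# (presence/absence of expression); per cluster, each gene's detection
# rate is compared between the two conditions at cell level with a
# Wilcoxon rank-sum test (exact by enumeration for small groups,
# tie-corrected continuity-corrected normal approximation otherwise) and
# at sample level with a two-sample t-test on per-sample CDRs. Genes are
# ranked by CDR ratio (second condition over reference by default).

#' Binarize a count matrix
#'
#' Entry 1 where the count is strictly positive, 0 elsewhere; the sparsity
#' structure is unchanged and the operation is idempotent.
#'
#' @param m a [CountMatrix], `LogExpressionMatrix`, or sparse/dense matrix.
#' @return a sparse `dgCMatrix` of 0/1 values (cells x genes) with
#'   dimnames preserved.
#' @export
binarize <- function(m) {
  x <- if (inherits(m, "CountMatrix")) m$counts
       else if (inherits(m, "LogExpressionMatrix")) m$values
       else m
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  x <- Matrix::drop0(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"))
  x@x <- rep(1, length(x@x))
  x
}

#' Detection rates per gene per group within a cluster
#'
#' Mean of the binarized column over the group's cells in the cluster,
#' i.e. the proportion of that group's cells expressing the gene.
#'
#' @param b binary matrix (cells x genes) as returned by [binarize()],
#'   with barcodes as rownames.
#' @param meta `CellMetadata`.
#' @param cluster cluster label.
#' @param grouping `"condition"` or `"sample"`.
#' @return matrix of proportions, genes x groups. Empty groups are omitted
#'   with a warning.
#' @export
cdr_by_group <- function(b, meta, cluster, grouping = c("condition", "sample")) {
  grouping <- match.arg(grouping)
  meta <- as_cell_metadata(meta)
  idx <- match(rownames(b), meta$barcode)
  if (anyNA(idx)) stop("metadata is missing ", sum(is.na(idx)), " barcode(s)")
  meta <- meta[idx, , drop = FALSE]
  in_cl <- meta$cluster == cluster
  if (!any(in_cl)) stop("cluster '", cluster, "' is empty")
  g <- as.character(meta[[grouping]])[in_cl]
  bb <- b[in_cl, , drop = FALSE]
  groups <- if (grouping == "condition") levels(meta$condition) else sort(unique(g))
  empty <- setdiff(groups, unique(g))
  if (length(empty)) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
    groups <- setdiff(groups, empty)
  }
  out <- vapply(groups, function(l) {
    Matrix::colMeans(bb[g == l, , drop = FALSE])
  }, numeric(ncol(bb)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(groups),
                                       dimnames = list(colnames(bb), groups))
  out
}

# Exact two-sided p for the rank-sum test on binary data. Given the total
# number of ones, the rank-sum statistic is a monotone function of the
# number of ones in group A, which is hypergeometric under the null; the
# two-sided p sums the probabilities of counts at least as far from their
# expectation as the observed one.
.wilcox_binary_exact <- function(nA, nB, xA, m1) {
  n <- nA + nB
  k <- max(0L, m1 - nB):min(nA, m1)
  pr <- stats::dhyper(k, m1, n - m1, nA)
  e <- nA * m1 / n
  min(1, sum(pr[abs(k - e) >= abs(xA - e) - 1e-9]))
}

# Tie-corrected, continuity-corrected normal approximation (the standard
# large-sample rank-sum treatment), specialized to binary data where the
# only tie groups are the zeros and the ones.
.wilcox_binary_normal <- function(nA, nB, xA, m1) {
  n <- nA + nB
  xB <- m1 - xA
  U <- xA * (nB - xB) + 0.5 * ((nA - xA) * (nB - xB) + xA * xB)
  mu <- nA * nB / 2
  ties <- c(n - m1, m1)
  sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum test on a binary detection vector
#'
#' Two-sided rank-sum (Mann-Whitney) test of the binarized expression
#' values between two groups of cells. When the smaller group has at most
#' `exact_max_n` cells the p-value is exact, by enumeration over the
#' hypergeometric distribution the ties induce; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param b_gene binary (0/1) values over cells.
#' @param groups two-level factor of condition labels.
#' @param exact_max_n group-size bound for the exact path.
#' @return two-sided p-value.
#' @export
wilcoxon_cdr_test <- function(b_gene, groups, exact_max_n = 8) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("groups must have exactly two non-empty levels")
  stopifnot(all(b_gene %in% c(0, 1)))
  a <- groups == levels(groups)[1L]
  nA <- sum(a); nB <- sum(!a)
  xA <- sum(b_gene[a]); m1 <- sum(b_gene)
  if (min(nA, nB) <= exact_max_n) {
    .wilcox_binary_exact(nA, nB, xA, m1)
  } else {
    .wilcox_binary_normal(nA, nB, xA, m1)
  }
}

#' Two-sample t-test on per-sample CDRs
#'
#' Two-sided two-sample t-test comparing per-sample detection-rate
#' proportions between conditions; pooled-variance Student's test by
#' default, Welch optionally. If both groups have zero variance the test
#' is degenerate: p = 1 for equal means, the smallest representable
#' p-value (flagged via attribute `degenerate`) otherwise.
#'
#' @param cdrs_a per-sample CDRs, condition A (>= 2 samples).
#' @param cdrs_b per-sample CDRs, condition B (>= 2 samples).
#' @param var_equal pooled-variance Student's test (default TRUE).
#' @return two-sided p-value.
#' @export
ttest_cdr <- function(cdrs_a, cdrs_b, var_equal = TRUE) {
  if (length(cdrs_a) < 2L || length(cdrs_b) < 2L) {
    stop("need at least 2 samples per group")
  }
  if (stats::var(cdrs_a) == 0 && stats::var(cdrs_b) == 0) {
    if (mean(cdrs_a) == mean(cdrs_b)) return(1)
    return(structure(.Machine$double.xmin, degenerate = TRUE))
  }
  stats::t.test(cdrs_a, cdrs_b, var.equal = var_equal)$p.value
}

#' CDR table for one cluster
#'
#' Computes, for each gene within the cluster: detection rates per
#' condition (`cdr_condA` = reference level, `cdr_condB` = other level)
#' and per sample (`cdr_sample_<id>` columns), the cell-level Wilcoxon
#' rank-sum p-value on the binarized values, its BH adjustment within the
#' cluster, the sample-level t-test p-value on per-sample CDRs (NA when a
#' condition has fewer than 2 samples), and the CDR ratio
#' `cdr_condB / cdr_condA` (NA and flagged when the denominator is 0).
#'
#' @param m a [CountMatrix] or `LogExpressionMatrix` (only presence/absence
#'   is used).
#' @param meta `CellMetadata`.
#' @param cluster cluster label.
#' @param var_equal passed to [ttest_cdr()].
#' @param exact_max_n passed to [wilcoxon_cdr_test()].
#' @return a `data.frame` (CdrTable).
#' @export
run_cdr <- function(m, meta, cluster, var_equal = TRUE, exact_max_n = 8) {
  b <- binarize(m)
  meta <- as_cell_metadata(meta)
  idx <- match(rownames(b), meta$barcode)
  if (anyNA(idx)) stop("metadata is missing ", sum(is.na(idx)), " barcode(s)")
  meta <- meta[idx, , drop = FALSE]
  in_cl <- which(meta$cluster == cluster)
  if (!length(in_cl)) stop("cluster '", cluster, "' is empty")
  cond <- droplevels(meta$condition[in_cl])
  if (nlevels(cond) != 2L) stop("cluster '", cluster, "' lacks both conditions")
  lvls <- levels(cond)
  bb <- b[in_cl, , drop = FALSE]

  a <- cond == lvls[1L]
  nA <- sum(a); nB <- sum(!a)
  xA <- Matrix::colSums(bb[a, , drop = FALSE])
  xB <- Matrix::colSums(bb[!a, , drop = FALSE])
  cdrA <- xA / nA
  cdrB <- xB / nB

  m1 <- xA + xB
  wil <- if (min(nA, nB) <= exact_max_n) {
    vapply(seq_along(xA), function(g) .wilcox_binary_exact(nA, nB, xA[g], m1[g]),
           numeric(1))
  } else {
    vapply(seq_along(xA), function(g) .wilcox_binary_normal(nA, nB, xA[g], m1[g]),
           numeric(1))
  }

  smp <- meta$sample[in_cl]
  sample_ids <- unique(smp)
  cdr_s <- vapply(sample_ids, function(s) {
    Matrix::colMeans(bb[smp == s, , drop = FALSE])
  }, numeric(ncol(bb)))
  sample_cond <- vapply(sample_ids,
                        function(s) as.character(cond[smp == s][1L]), "")
  tp <- rep(NA_real_, ncol(bb))
  if (sum(sample_cond == lvls[1L]) >= 2L && sum(sample_cond == lvls[2L]) >= 2L) {
    ia <- sample_cond == lvls[1L]
    tp <- vapply(seq_len(ncol(bb)), function(g) {
      as.numeric(ttest_cdr(cdr_s[g, ia], cdr_s[g, !ia], var_equal = var_equal))
    }, numeric(1))
  }

  out <- data.frame(
    gene = colnames(bb), cluster = cluster,
    cdr_condA = as.numeric(cdrA), cdr_condB = as.numeric(cdrB),
    wilcoxon_p = wil, cdr_fdr = bh_adjust(wil), ttest_p = tp,
    cdr_ratio = ifelse(cdrA > 0, cdrB / cdrA, NA_real_),
    zero_denominator = cdrA == 0 & cdrB > 0,
    stringsAsFactors = FALSE
  )
  cs <- as.data.frame(cdr_s)
  names(cs) <- paste0("cdr_sample_", sample_ids)
  out <- cbind(out, cs)
  rownames(out) <- NULL
  attr(out, "condition_levels") <- lvls
  attr(out, "n_cells") <- c(nA, nB)
  class(out) <- c("CdrTable", "data.frame")
  out
}

#' Rank genes by CDR ratio
#'
#' Partitions genes by ratio direction and ranks each direction by
#' `|log(cdr_ratio)|` descending, returning the top `k`. With the default
#' orientation (`cdr_ratio = cdr_condB / cdr_condA`, i.e. SPMS over RRMS
#' when those are the condition labels), direction `"A>B"` collects genes
#' with ratio < 1 and `"B>A"` genes with ratio > 1. Genes with equal CDRs
#' are excluded from both lists; genes detected in B but never in A (zero
#' denominator) rank first within `"B>A"` with `zero_denominator = TRUE`.
#'
#' @param table a CdrTable from [run_cdr()].
#' @param direction `"B>A"` or `"A>B"`.
#' @param k number of genes to return (> 0).
#' @return the top-k rows of `table`, ranked, with a `rank` column.
#' @export
cdr_ratio_rank <- function(table, direction = c("B>A", "A>B"), k = 30) {
  direction <- match.arg(direction)
  if (k <= 0) stop("k must be positive")
  stopifnot(all(c("cdr_condA", "cdr_condB") %in% names(table)))
  lr <- log(table$cdr_condB) - log(table$cdr_condA)  # Inf/-Inf/NaN handled below
  keep <- if (direction == "B>A") {
    table$cdr_condB > table$cdr_condA
  } else {
    table$cdr_condA > table$cdr_condB
  }
  keep[is.na(keep)] <- FALSE
  sub <- table[keep, , drop = FALSE]
  score <- abs(lr[keep])  # Inf for zero-denominator genes: ranked first
  ord <- order(-score, sub$gene)
  sub <- sub[ord, , drop = FALSE]
  sub <- utils::head(sub, k)
  sub$rank <- seq_len(nrow(sub))
  rownames(sub) <- NULL
  sub
}
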