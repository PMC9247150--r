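#' Construct a cell-by-gene UMI count matrix
#'
#' `CountMatrix` is the package's container for droplet-based UMI counts:
#' a sparse cells x genes matrix together with gene identifiers, display
#' symbols, cell barcodes and the sample each cell came from. External
#' MatrixMarket files follow the Cell Ranger genes x cells orientation;
#' internally everything is cells x genes so per-cell operations are
#' row-wise.
#'
#' @param counts sparse (or dense) non-negative integer matrix,
#'   cells x genes.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column.
#' @param gene_symbols display symbols; may contain duplicates (all joins
#'   in the package are keyed on `gene_ids`).
#' @param barcodes unique cell identifiers, one per row.
#' @param sample_of_cell sample identifier per cell; recycled if length 1.
#'
#' @return An object of class `CountMatrix`: a list with elements
#'   `counts` (a `dgCMatrix`), `gene_ids`, `gene_symbols`, `barcodes`,
#'   `sample_of_cell`.
#' @export
CountMatrix <- function(counts, gene_ids, gene_symbols = gene_ids,
                        barcodes, sample_of_cell) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  counts <- Matrix::drop0(counts)
  if (length(sample_of_cell) == 1L) {
    sample_of_cell <- rep(sample_of_cell, nrow(counts))
  }
  obj <- structure(
    list(
      counts = counts,
      gene_ids = as.character(gene_ids),
      gene_symbols = as.character(gene_symbols),
      barcodes = as.character(barcodes),
      sample_of_cell = as.character(sample_of_cell)
    ),
    class = "CountMatrix"
  )
  validate_count_matrix(obj)
  dimnames(obj$counts) <- list(obj$barcodes, obj$gene_ids)
  obj
}

#' Validate a CountMatrix
#'
#' Checks the container invariants: non-negative integer counts, matching
#' dimensions, unique gene ids and unique barcodes.
#'
#' @param m a `CountMatrix`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_count_matrix <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  x <- m$counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  if (nrow(m$counts) != length(m$barcodes)) {
    stop("number of rows (", nrow(m$counts), ") != number of barcodes (",
         length(m$barcodes), ")")
  }
  if (ncol(m$counts) != length(m$gene_ids)) {
    stop("number of columns (", ncol(m$counts), ") != number of gene ids (",
         length(m$gene_ids), ")")
  }
  if (length(m$gene_symbols) != length(m$gene_ids)) {
    stop("gene_symbols and gene_ids lengths differ")
  }
  if (anyDuplicated(m$gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(m$barcodes)) stop("barcodes must be unique")
  if (length(m$sample_of_cell) != length(m$barcodes)) {
    stop("sample_of_cell must have one entry per cell")
  }
  invisible(m)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf(
    "CountMatrix: %d cells x %d genes, %d samples, %.0f total UMIs\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$sample_of_cell)),
    sum(x$counts@x)
  ))
  invisible(x)
}

#' Subset a CountMatrix by cells and/or genes
#'
#' @param m a `CountMatrix`.
#' @param cells logical/integer/character index over cells (rows).
#' @param genes logical/integer/character index over genes (columns).
#' @return the subset `CountMatrix`.
#' @export
cm_subset <- function(m, cells = NULL, genes = NULL) {
  validate_count_matrix(m)
  ci <- seq_len(nrow(m$counts))
  gi <- seq_len(ncol(m$counts))
  if (!is.null(cells)) {
    ci <- if (is.character(cells)) match(cells, m$barcodes) else ci[cells]
  }
  if (!is.null(genes)) {
    gi <- if (is.character(genes)) match(genes, m$gene_ids) else gi[genes]
  }
  if (anyNA(ci) || anyNA(gi)) stop("unknown barcode or gene id in subset")
  CountMatrix(
    counts = m$counts[ci, gi, drop = FALSE],
    gene_ids = m$gene_ids[gi],
    gene_symbols = m$gene_symbols[gi],
    barcodes = m$barcodes[ci],
    sample_of_cell = m$sample_of_cell[ci]
  )
}

#' Concatenate per-sample count matrices over the union of genes
#'
#' Genes absent from a sample are kept as all-zero columns so downstream
#' stages operate on a common gene space. Gene order is first occurrence
#' across the input list. If barcodes collide across samples every barcode
#' is suffixed with `-<sampleID>`; total UMI counts are preserved exactly.
#'
#' @param samples list of `CountMatrix` objects.
#' @return a single combined `CountMatrix`.
#' @export
bind_samples <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  lapply(samples, validate_count_matrix)
  if (length(samples) == 1L) return(samples[[1L]])

  all_ids <- unique(unlist(lapply(samples, `[[`, "gene_ids")))
  sym <- character(length(all_ids))
  names(sym) <- all_ids
  for (s in rev(samples)) sym[s$gene_ids] <- s$gene_symbols

  bc_all <- unlist(lapply(samples, `[[`, "barcodes"), use.names = FALSE)
  suffix <- anyDuplicated(bc_all) > 0L

  mats <- vector("list", length(samples))
  barcodes <- character(0)
  sample_of_cell <- character(0)
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    tri <- Matrix::mat2triplet(s$counts)
    j_new <- match(s$gene_ids, all_ids)[tri$j]
    mats[[k]] <- Matrix::sparseMatrix(
      i = tri$i, j = j_new, x = tri$x,
      dims = c(nrow(s$counts), length(all_ids))
    )
    bc <- s$barcodes
    if (suffix) bc <- paste0(bc, "-", s$sample_of_cell)
    barcodes <- c(barcodes, bc)
    sample_of_cell <- c(sample_of_cell, s$sample_of_cell)
  }
  CountMatrix(
    counts = do.call(rbind, mats),
    gene_ids = all_ids,
    gene_symbols = unname(sym),
    barcodes = barcodes,
    sample_of_cell = sample_of_cell
  )
}
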