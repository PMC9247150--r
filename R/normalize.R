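# Library-size log normalization. The hurdle model's continuous part
# operates on log2 counts-per-scale_factor values; zeros stay exactly
# zero so the detection (hurdle) axis is preserved.

#' Log-normalize a QC'd count matrix
#'
#' Computes `log2(1 + scale_factor * count / total)` per cell, where
#' `total` is the cell's total UMI count. The sparsity pattern is
#' preserved: the value is 0 exactly where the raw count is 0.
#'
#' @param m a [CountMatrix] that passed QC (no zero-total cells).
#' @param scale_factor counts-per-cell target (default 10,000, i.e.
#'   log2-CP10K).
#' @return an object of class `LogExpressionMatrix`: list with `values`
#'   (sparse cells x genes `dgCMatrix`), `scale_factor`, `gene_ids`,
#'   `gene_symbols`, `barcodes`, `sample_of_cell`.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  validate_count_matrix(m)
  stopifnot(scale_factor > 0)
  totals <- Matrix::rowSums(m$counts)
  if (any(totals == 0)) {
    stop(sum(totals == 0), " cell(s) have zero total counts; ",
         "run QC before normalization")
  }
  v <- m$counts
  # dgCMatrix stores @x column-wise; @i are 0-based row (cell) indices
  v@x <- log2(1 + scale_factor * v@x / totals[v@i + 1L])
  structure(
    list(
      values = v,
      scale_factor = scale_factor,
      gene_ids = m$gene_ids,
      gene_symbols = m$gene_symbols,
      barcodes = m$barcodes,
      sample_of_cell = m$sample_of_cell
    ),
    class = "LogExpressionMatrix"
  )
}

#' @export
dim.LogExpressionMatrix <- function(x) dim(x$values)

#' @export
print.LogExpressionMatrix <- function(x, ...) {
  cat(sprintf("LogExpressionMatrix: %d cells x %d genes (log2, scale %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}
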