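# Readers/writers for the 10x triplet exchange format, the cell-metadata
# table and the pipeline's tabular outputs. MTX files on disk follow the
# Cell Ranger genes x cells orientation; CountMatrix is cells x genes.

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

.find_triplet_file <- function(directory, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(directory, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop("format error: no ", stems[1L], "[.gz] found in ", directory)
}

#' Read a 10x Genomics triplet directory
#'
#' Reads `matrix.mtx[.gz]` (MatrixMarket coordinate, genes x cells),
#' `features.tsv[.gz]` (or `genes.tsv`) and `barcodes.tsv[.gz]` and returns
#' a cells x genes [CountMatrix] with counts preserved exactly.
#'
#' @param directory path containing the three files.
#' @param sample_id sample label assigned to every cell; defaults to the
#'   directory name.
#' @return a [CountMatrix].
#' @export
read_10x_mtx <- function(directory, sample_id = basename(normalizePath(directory))) {
  if (!dir.exists(directory)) stop("format error: directory not found: ", directory)
  mtx_path <- .find_triplet_file(directory, "matrix.mtx")
  feat_path <- .find_triplet_file(directory, c("features.tsv", "genes.tsv"))
  bc_path <- .find_triplet_file(directory, "barcodes.tsv")

  mm <- Matrix::readMM(.open_maybe_gz(mtx_path))
  feats <- utils::read.delim(.open_maybe_gz(feat_path), header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(.open_maybe_gz(bc_path), header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]

  if (nrow(mm) != nrow(feats)) {
    stop("integrity error: matrix has ", nrow(mm), " genes but features table has ",
         nrow(feats), " rows")
  }
  if (ncol(mm) != length(barcodes)) {
    stop("integrity error: matrix has ", ncol(mm), " cells but barcodes table has ",
         length(barcodes), " rows")
  }
  CountMatrix(
    counts = Matrix::t(mm),
    gene_ids = feats[[1L]],
    gene_symbols = if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]],
    barcodes = barcodes,
    sample_of_cell = sample_id
  )
}

#' Write a CountMatrix as a 10x triplet directory
#'
#' Emits `matrix.mtx` (genes x cells), `features.tsv` (id, symbol, type)
#' and `barcodes.tsv` so that [read_10x_mtx()] reproduces the counts
#' bit-exactly.
#'
#' @param m a [CountMatrix].
#' @param directory output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_10x_mtx <- function(m, directory) {
  validate_count_matrix(m)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(directory, "matrix.mtx"))
  utils::write.table(
    data.frame(m$gene_ids, m$gene_symbols, "Gene Expression"),
    file.path(directory, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  writeLines(m$barcodes, file.path(directory, "barcodes.tsv"))
  invisible(directory)
}

.metadata_required_cols <- c("barcode", "sample", "condition", "cluster",
                             "sex", "age", "rin")

#' Read the cell-metadata table
#'
#' The table must carry one row per cell with columns `barcode`, `sample`,
#' `condition`, `cluster`, `sex`, `age`, `rin`. The per-sample covariates
#' (`condition`, `sex`, `age`, `rin`) must be constant within each sample.
#' `condition` is returned as a factor whose first (reference) level is the
#' alphabetically first label, so with the RRMS/SPMS contrast RRMS is the
#' reference.
#'
#' @param path a delimited (tab-separated) file.
#' @return a `data.frame` of class `CellMetadata` with typed columns in a
#'   deterministic order.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("format error: metadata file not found: ", path)
  df <- utils::read.delim(.open_maybe_gz(path), stringsAsFactors = FALSE)
  as_cell_metadata(df)
}

#' Coerce a data.frame to CellMetadata
#'
#' @param df data.frame with the required metadata columns.
#' @return validated `CellMetadata` data.frame.
#' @export
as_cell_metadata <- function(df) {
  missing_cols <- setdiff(.metadata_required_cols, names(df))
  if (length(missing_cols)) {
    stop("schema error: metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, c(.metadata_required_cols,
               setdiff(names(df), .metadata_required_cols)), drop = FALSE]
  df$barcode <- as.character(df$barcode)
  df$sample <- as.character(df$sample)
  df$condition <- factor(df$condition)
  df$cluster <- as.character(df$cluster)
  df$sex <- factor(df$sex)
  df$age <- as.numeric(df$age)
  df$rin <- as.numeric(df$rin)
  if (anyDuplicated(df$barcode)) stop("schema error: duplicated barcodes in metadata")
  if (nlevels(df$condition) > 2L) {
    stop("schema error: more than two condition labels")
  }
  for (col in c("condition", "sex", "age", "rin")) {
    n_per_sample <- tapply(df[[col]], df$sample, function(v) length(unique(v)))
    bad <- names(n_per_sample)[n_per_sample > 1L]
    if (length(bad)) {
      stop("consistency error: '", col, "' varies within sample(s): ",
           paste(bad, collapse = ", "))
    }
  }
  class(df) <- c("CellMetadata", "data.frame")
  df
}

#' Write a pipeline result table as TSV
#'
#' Tab-separated, header line, stable column order, full-precision floats
#' (15 significant digits), so that re-reading reproduces values to at
#' least 12 significant digits.
#'
#' @param table a data.frame (DGE, CDR or VAG table, QC report, ...).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- sprintf("%.15g", out[[j]])
      out[[j]][out[[j]] %in% c("NA", "nan")] <- NA
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path TSV file path.
#' @return a data.frame.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
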