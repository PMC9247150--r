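# Per-sample quality-control cascade for single-nucleus UMI matrices:
#   1. drop genes detected in fewer than `min_cells_per_gene` nuclei;
#   2. drop nuclei expressing fewer than `min_genes_per_cell` genes;
#   3. drop nuclei with mitochondrial count fraction above
#      `max_mito_fraction` OR total transcript count above
#      Q(outlier_quantile) + outlier_iqr_mult * IQR (dying cells and
#      multiplets), with quantiles computed on the cells surviving the
#      earlier steps.
# All thresholds are computed within a single sample, never on the pooled
# matrix.

#' QC threshold settings
#'
#' Defaults encode the filtering cascade used for the RRMS/SPMS nuclei:
#' genes must be detected in at least 3 nuclei, nuclei must express at
#' least 300 genes, nuclei with more than 1 percent mitochondrial counts
#' or with total transcript counts above the 75th percentile + 1.5 x IQR
#' of their sample are excluded.
#'
#' @param min_cells_per_gene minimum number of nuclei a gene must be
#'   detected in (count > 0) to be retained.
#' @param min_genes_per_cell minimum number of genes a nucleus must
#'   express (inclusive bound).
#' @param max_mito_fraction mitochondrial count fraction above which
#'   (strictly) a nucleus is excluded.
#' @param outlier_quantile quantile the transcript-count outlier rule is
#'   anchored at.
#' @param outlier_iqr_mult IQR multiplier of the outlier rule.
#' @param mito_prefix case-insensitive gene-symbol prefix identifying
#'   mitochondrial genes (human nomenclature `"MT-"`).
#' @param quantile_type quantile convention passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics).
#' @return a list of class `QcThresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3,
                          min_genes_per_cell = 300,
                          max_mito_fraction = 0.01,
                          outlier_quantile = 0.75,
                          outlier_iqr_mult = 1.5,
                          mito_prefix = "MT-",
                          quantile_type = 7) {
  stopifnot(
    min_cells_per_gene >= 0, min_genes_per_cell >= 0,
    max_mito_fraction >= 0, max_mito_fraction <= 1,
    outlier_quantile > 0, outlier_quantile < 1,
    outlier_iqr_mult >= 0
  )
  structure(
    list(
      min_cells_per_gene = min_cells_per_gene,
      min_genes_per_cell = min_genes_per_cell,
      max_mito_fraction = max_mito_fraction,
      outlier_quantile = outlier_quantile,
      outlier_iqr_mult = outlier_iqr_mult,
      mito_prefix = mito_prefix,
      quantile_type = quantile_type
    ),
    class = "QcThresholds"
  )
}

#' Filter genes by number of nuclei they are detected in
#'
#' Retains genes with a nonzero count in at least `min_cells` cells of
#' this matrix; column order is preserved. An empty result is allowed.
#'
#' @param m a [CountMatrix] (one sample).
#' @param min_cells detection-count threshold (inclusive).
#' @return the filtered [CountMatrix].
#' @export
gene_filter <- function(m, min_cells = 3) {
  validate_count_matrix(m)
  stopifnot(min_cells >= 0)
  detected_in <- Matrix::colSums(m$counts > 0)
  cm_subset(m, genes = detected_in >= min_cells)
}

#' Filter cells by number of expressed genes
#'
#' Retains cells expressing (count > 0) at least `min_genes` genes; the
#' bound is inclusive, so a nucleus with exactly `min_genes` genes is
#' kept.
#'
#' @param m a [CountMatrix].
#' @param min_genes minimum expressed-gene count.
#' @return the filtered [CountMatrix].
#' @export
cell_gene_count_filter <- function(m, min_genes = 300) {
  validate_count_matrix(m)
  stopifnot(min_genes >= 0)
  genes_per_cell <- Matrix::rowSums(m$counts > 0)
  cm_subset(m, cells = genes_per_cell >= min_genes)
}

#' Per-cell mitochondrial count fraction
#'
#' Fraction of each cell's total UMIs falling on genes whose symbol starts
#' with `mito_prefix` (case-insensitive). Cells with zero total counts get
#' fraction 0 by convention.
#'
#' @param m a [CountMatrix].
#' @param mito_prefix gene-symbol prefix.
#' @return numeric vector, one fraction per cell.
#' @export
mito_fraction <- function(m, mito_prefix = "MT-") {
  validate_count_matrix(m)
  is_mito <- startsWith(toupper(m$gene_symbols), toupper(mito_prefix))
  if (!any(is_mito)) {
    warning("no gene symbol matches mitochondrial prefix '", mito_prefix,
            "'; all fractions set to 0")
    return(rep(0, nrow(m$counts)))
  }
  totals <- Matrix::rowSums(m$counts)
  mito <- Matrix::rowSums(m$counts[, is_mito, drop = FALSE])
  frac <- ifelse(totals > 0, mito / totals, 0)
  as.numeric(frac)
}

#' Transcript-count outlier threshold
#'
#' Returns `Q(q) + k * (Q(0.75) - Q(0.25))` of the per-cell total UMI
#' counts of one sample. Cells whose totals are strictly greater than the
#' threshold are treated as multiplet-like outliers.
#'
#' @param totals per-cell total transcript counts (at least one cell).
#' @param q anchoring quantile.
#' @param k IQR multiplier.
#' @param type quantile convention (see [stats::quantile()]).
#' @return the threshold (scalar).
#' @export
transcript_outlier_threshold <- function(totals, q = 0.75, k = 1.5, type = 7) {
  stopifnot(length(totals) >= 1)
  qs <- stats::quantile(totals, c(q, 0.25, 0.75), type = type, names = FALSE)
  qs[1L] + k * (qs[3L] - qs[2L])
}

#' Apply the full QC cascade to one sample
#'
#' Applies, in order: [gene_filter()], [cell_gene_count_filter()], then a
#' simultaneous OR of the mitochondrial-fraction and transcript-outlier
#' exclusions, with the outlier threshold computed on the cells surviving
#' the earlier steps. A cell failing both of the OR'd rules is attributed
#' to the mitochondrial rule (first-triggering attribution). If every cell
#' is removed a warning is recorded in the report rather than thrown.
#'
#' @param m a [CountMatrix] holding exactly one sample.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with elements `matrix` (filtered [CountMatrix]) and
#'   `report` (one-row data.frame of class `QcReport`).
#' @export
apply_qc <- function(m, thresholds = qc_thresholds()) {
  validate_count_matrix(m)
  t <- thresholds
  stopifnot(inherits(t, "QcThresholds"))
  sample_id <- unique(m$sample_of_cell)
  if (length(sample_id) != 1L) {
    stop("apply_qc operates on one sample; got ", length(sample_id),
         " (use apply_qc_samples for multi-sample matrices)")
  }
  n_cells_in <- nrow(m$counts)
  n_genes_in <- ncol(m$counts)

  m1 <- gene_filter(m, t$min_cells_per_gene)
  genes_removed <- n_genes_in - ncol(m1$counts)

  m2 <- cell_gene_count_filter(m1, t$min_genes_per_cell)
  removed_min_genes <- nrow(m1$counts) - nrow(m2$counts)

  outlier_threshold <- NA_real_
  removed_mito <- 0L
  removed_outlier <- 0L
  if (nrow(m2$counts) > 0L) {
    frac <- suppressWarnings(mito_fraction(m2, t$mito_prefix))
    totals <- as.numeric(Matrix::rowSums(m2$counts))
    outlier_threshold <- transcript_outlier_threshold(
      totals, t$outlier_quantile, t$outlier_iqr_mult, t$quantile_type
    )
    fail_mito <- frac > t$max_mito_fraction
    fail_outlier <- totals > outlier_threshold
    removed_mito <- sum(fail_mito)
    removed_outlier <- sum(fail_outlier & !fail_mito)
    m3 <- cm_subset(m2, cells = !(fail_mito | fail_outlier))
  } else {
    m3 <- m2
  }

  warn <- if (nrow(m3$counts) == 0L) "all cells removed" else NA_character_
  report <- data.frame(
    sample = sample_id,
    n_cells_in = n_cells_in,
    n_genes_in = n_genes_in,
    genes_removed = genes_removed,
    cells_removed_min_genes = removed_min_genes,
    cells_removed_mito = removed_mito,
    cells_removed_outlier = removed_outlier,
    outlier_threshold = outlier_threshold,
    n_cells_out = nrow(m3$counts),
    n_genes_out = ncol(m3$counts),
    filter_order = "gene_filter;min_genes;mito|outlier",
    warning = warn,
    stringsAsFactors = FALSE
  )
  class(report) <- c("QcReport", "data.frame")
  list(matrix = m3, report = report)
}

#' Apply QC per sample and re-concatenate
#'
#' Splits a multi-sample matrix by sample, runs [apply_qc()] on each
#' sample independently (all thresholds computed within the sample) and
#' re-binds the survivors over the union of retained genes; genes absent
#' from a sample after its gene filter are kept as zeros.
#'
#' @param m a multi-sample [CountMatrix].
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `matrix` (combined filtered [CountMatrix]) and
#'   `report` (data.frame with one row per sample).
#' @export
apply_qc_samples <- function(m, thresholds = qc_thresholds()) {
  validate_count_matrix(m)
  ids <- unique(m$sample_of_cell)
  res <- lapply(ids, function(s) {
    apply_qc(cm_subset(m, cells = m$sample_of_cell == s), thresholds)
  })
  kept <- Filter(function(r) nrow(r$matrix$counts) > 0, res)
  if (!length(kept)) stop("QC removed every cell in every sample")
  report <- do.call(rbind, lapply(res, `[[`, "report"))
  class(report) <- c("QcReport", "data.frame")
  list(matrix = bind_samples(lapply(kept, `[[`, "matrix")), report = report)
}
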