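# Vastly altered genes (VAGs): the per-cluster intersection of the DEG
# set and the set of genes with significant detection-rate (CDR) change.

#' Extract vastly altered genes for one cluster
#'
#' Intersects, by gene id, the DEGs of a cluster (`is_deg` in the
#' DgeTable) with the genes whose CDR change is significant
#' (`cdr_fdr < cdr_fdr_threshold` in the CdrTable) and joins the evidence
#' from both tables. Rows are ordered by gene id. The `direction` column
#' gives the condition the gene is up in (from the sign of `log2fc`);
#' genes whose log2 fold change and CDR difference disagree in sign are
#' flagged `discordant` but retained.
#'
#' @param dge DgeTable from [run_dge()] (one cluster).
#' @param cdr CdrTable from [run_cdr()] (same cluster).
#' @param cdr_fdr_threshold significance cutoff for the CDR evidence.
#' @return a `data.frame` (VagTable) with gene, cluster, the DEG evidence
#'   (`log2fc`, `dge_fdr`), the CDR evidence (`cdr_condA`, `cdr_condB`,
#'   `cdr_fdr`), `direction` and `discordant`.
#' @export
extract_vags <- function(dge, cdr, cdr_fdr_threshold = 0.05) {
  stopifnot(is.data.frame(dge), is.data.frame(cdr))
  cl_d <- unique(dge$cluster)
  cl_c <- unique(cdr$cluster)
  if (length(cl_d) != 1L || length(cl_c) != 1L || cl_d != cl_c) {
    stop("cluster mismatch: DGE table is for '", paste(cl_d, collapse = ","),
         "', CDR table for '", paste(cl_c, collapse = ","), "'")
  }
  deg_genes <- dge$gene[dge$is_deg %in% TRUE]
  sig_cdr <- cdr$gene[!is.na(cdr$cdr_fdr) & cdr$cdr_fdr < cdr_fdr_threshold]
  vag_genes <- sort(intersect(deg_genes, sig_cdr))

  di <- match(vag_genes, dge$gene)
  ci <- match(vag_genes, cdr$gene)
  lvls <- attr(dge, "condition_levels")
  if (is.null(lvls)) lvls <- c("A", "B")
  log2fc <- dge$log2fc[di]
  cdr_diff <- cdr$cdr_condB[ci] - cdr$cdr_condA[ci]
  out <- data.frame(
    gene = vag_genes,
    cluster = if (length(vag_genes)) cl_d else character(0),
    log2fc = log2fc,
    dge_fdr = dge$fdr[di],
    cdr_condA = cdr$cdr_condA[ci],
    cdr_condB = cdr$cdr_condB[ci],
    cdr_fdr = cdr$cdr_fdr[ci],
    direction = ifelse(log2fc > 0, paste0("up-in-", lvls[2L]),
                       paste0("up-in-", lvls[1L])),
    discordant = sign(log2fc) != sign(cdr_diff) & cdr_diff != 0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("VagTable", "data.frame")
  out
}

#' Venn counts of DEGs vs significant-CDR genes
#'
#' @inheritParams extract_vags
#' @return named integer vector `c(deg_only, cdr_only, intersection)`.
#' @export
venn_counts <- function(dge, cdr, cdr_fdr_threshold = 0.05) {
  deg_genes <- unique(dge$gene[dge$is_deg %in% TRUE])
  sig_cdr <- unique(cdr$gene[!is.na(cdr$cdr_fdr) &
                               cdr$cdr_fdr < cdr_fdr_threshold])
  both <- length(intersect(deg_genes, sig_cdr))
  c(deg_only = length(deg_genes) - both,
    cdr_only = length(sig_cdr) - both,
    intersection = both)
}
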