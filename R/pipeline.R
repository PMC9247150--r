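# End-to-end orchestration: simulate (or ingest) -> per-sample QC ->
# log normalization -> per-cluster hurdle DGE -> per-cluster CDR ->
# VAG extraction, with TSV/JSON outputs and a run manifest. The contrast
# direction is fixed globally (reference condition = first factor level,
# RRMS under the default labels) so log2FC and CDR-ratio signs agree
# across all tables.

#' Pipeline configuration
#'
#' @param input either `NULL` (use `sim` to generate data), or a directory
#'   of per-sample 10x triplet subdirectories plus a `metadata.tsv`.
#' @param sim a [sim_config()] used when `input` is `NULL`.
#' @param qc a [qc_thresholds()].
#' @param dge a [dge_config()].
#' @param cdr_fdr_threshold significance rule for "significant CDR"
#'   (BH-adjusted cell-level Wilcoxon p within cluster).
#' @param ratio_direction which CDR-ratio direction to rank,
#'   `"B>A"` (SPMS over RRMS under the default labels) or `"A>B"`.
#' @param top_k size of the ranked CDR-ratio list.
#' @param clusters clusters to analyse; `NULL` = all in the metadata.
#' @param seed seed recorded into the manifest and forwarded to `sim`.
#' @return list of class `RunConfig`.
#' @export
pipeline_config <- function(input = NULL,
                            sim = sim_config(),
                            qc = qc_thresholds(),
                            dge = dge_config(),
                            cdr_fdr_threshold = 0.05,
                            ratio_direction = "B>A",
                            top_k = 30,
                            clusters = NULL,
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- seed
  structure(
    list(input = input, sim = sim, qc = qc, dge = dge,
         cdr_fdr_threshold = cdr_fdr_threshold,
         ratio_direction = ratio_direction, top_k = top_k,
         clusters = clusters, seed = if (is.null(seed)) sim$seed else seed),
    class = "RunConfig"
  )
}

.read_input_dir <- function(input) {
  meta_path <- file.path(input, "metadata.tsv")
  metadata <- read_metadata(meta_path)
  sample_dirs <- list.dirs(input, recursive = FALSE)
  if (!length(sample_dirs)) stop("no per-sample directories under ", input)
  samples <- lapply(sample_dirs, read_10x_mtx)
  list(samples = samples, metadata = metadata)
}

#' Run the whole pipeline
#'
#' Executes every stage and, when `out_dir` is given, writes per-cluster
#' `dge_<cluster>.tsv`, `cdr_<cluster>.tsv`, `vag_<cluster>.tsv`, the
#' ranked CDR-ratio lists, `qc_report.tsv`/`qc_report.json`, `venn.json`
#' and `manifest.json`. Reruns with the same config and seed reproduce
#' the output tables byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return (invisibly) a list with the QC'd matrix, normalized matrix,
#'   metadata, per-cluster `dge`/`cdr`/`vag` tables, `venn` counts, the
#'   ranked `cdr_top` lists, QC report, skipped-cluster reasons, manifest
#'   and, for simulated runs, the simulation output (`sim`).
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  sim_out <- NULL
  if (is.null(config$input)) {
    sim_out <- simulate_dataset(config$sim)
    samples <- sim_out$samples
    metadata <- sim_out$metadata
  } else {
    inp <- .read_input_dir(config$input)
    samples <- inp$samples
    metadata <- inp$metadata
  }

  qc <- apply_qc_samples(bind_samples(samples), config$qc)
  m <- qc$matrix
  keep <- m$barcodes %in% metadata$barcode
  if (!all(keep)) m <- cm_subset(m, cells = keep)
  x <- log_normalize(m)
  meta <- metadata[match(m$barcodes, metadata$barcode), , drop = FALSE]

  clusters <- config$clusters
  if (is.null(clusters)) clusters <- sort(unique(meta$cluster))

  dge <- list(); cdr <- list(); vag <- list()
  venn <- list(); cdr_top <- list(); skipped <- character(0)
  for (cl in clusters) {
    d <- run_dge(x, meta, cl, config$dge)
    if (is.null(d)) {
      skipped[cl] <- "too few cells in at least one condition"
      next
    }
    cc <- run_cdr(m, meta, cl)
    dge[[cl]] <- d
    cdr[[cl]] <- cc
    vag[[cl]] <- extract_vags(d, cc, config$cdr_fdr_threshold)
    venn[[cl]] <- as.list(venn_counts(d, cc, config$cdr_fdr_threshold))
    cdr_top[[cl]] <- cdr_ratio_rank(cc, config$ratio_direction, config$top_k)
  }

  manifest <- list(
    package = "vagex",
    version = as.character(utils::packageVersion("vagex")),
    seed = config$seed,
    input = if (is.null(config$input)) "simulated" else config$input,
    sim = if (is.null(config$input)) unclass(config$sim) else NULL,
    qc_thresholds = unclass(config$qc),
    dge_config = unclass(config$dge),
    cdr_fdr_threshold = config$cdr_fdr_threshold,
    ratio_direction = config$ratio_direction,
    top_k = config$top_k,
    clusters_run = names(dge),
    clusters_skipped = as.list(skipped)
  )

  res <- list(matrix = m, normalized = x, metadata = meta,
              qc_report = qc$report, dge = dge, cdr = cdr, vag = vag,
              venn = venn, cdr_top = cdr_top, skipped = skipped,
              manifest = manifest, sim = sim_out)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    safe <- function(s) gsub("[^A-Za-z0-9_.-]", "_", s)
    write_table(qc$report, file.path(out_dir, "qc_report.tsv"))
    jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                         dataframe = "rows", na = "null", digits = NA)
    for (cl in names(dge)) {
      write_table(dge[[cl]], file.path(out_dir, paste0("dge_", safe(cl), ".tsv")))
      write_table(cdr[[cl]], file.path(out_dir, paste0("cdr_", safe(cl), ".tsv")))
      write_table(vag[[cl]], file.path(out_dir, paste0("vag_", safe(cl), ".tsv")))
      write_table(cdr_top[[cl]],
                  file.path(out_dir, paste0("cdr_top_", safe(cl), ".tsv")))
    }
    jsonlite::write_json(venn, file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
  }
  invisible(res)
}
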