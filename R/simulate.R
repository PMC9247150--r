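# Seeded multi-sample snRNA-seq simulator. Counts follow a zero-inflated
# negative binomial: a logistic detection model (in the log latent mean)
# decides whether a gene is seen in a cell; detected entries draw a
# zero-truncated NB. Detection is deliberately decoupled from the planted
# expression effects so that expression-only, detection-only and joint
# (VAG-like) effect classes are distinguishable, which is what the
# DEG/CDR/VAG logic is meant to separate. A configurable fraction of
# "dying" cells gets strongly elevated mitochondrial counts to exercise
# the QC mito rule.

.default_cluster_proportions <- c(
  oligodendrocyte = 0.70,
  astrocyte = 0.09,
  excitatory_neuron = 0.06,
  OPC = 0.05,
  myeloid = 0.04,
  inhibitory_neuron = 0.03,
  endothelial = 0.015,
  pericyte = 0.01,
  lymphocyte = 0.005
)

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: 3 vs 5 samples
#' per condition (RRMS vs SPMS), a per-sample nucleus target, 9 cell-type
#' clusters with a dominant (~70%) oligodendrocyte cluster, log-normal
#' baseline NB means with gene-specific overdispersion, a logistic
#' dropout model in the log mean, 13 mitochondrial genes, per-sample
#' covariates (sex, age, RIN), and planted condition effects on the mean
#' (log2 shift), on the detection probability (logit shift), or on both
#' (the joint, VAG-like class).
#'
#' @param n_samples_per_condition samples per condition, reference first.
#' @param condition_labels the two condition names, reference first.
#' @param n_cells_per_sample nuclei per sample (1,000 default;
#'   5,000 for full study-scale runs).
#' @param n_genes total genes, including `n_mito_genes`.
#' @param n_mito_genes mitochondrial genes, symbols `MT-SIM1..`.
#' @param cluster_proportions named per-cell-type proportions (sum 1).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline NB mean
#'   distribution across genes.
#' @param cluster_factor_sdlog log-normal sd of gene x cluster factors.
#' @param sample_factor_sdlog log-normal sd of gene x sample factors
#'   (within-condition sample correlation; affects magnitude only).
#' @param nb_size_meanlog,nb_size_sdlog log-normal distribution of the NB
#'   size (inverse overdispersion) across genes.
#' @param dropout_intercept,dropout_slope logistic detection model:
#'   `logit(p_detect) = intercept + slope * log(mean)`.
#' @param mito_baseline_mean NB mean of each mitochondrial gene.
#' @param dying_cell_fraction fraction of cells with elevated mito counts.
#' @param dying_mito_multiplier factor applied to mito-gene means (and
#'   feeding the detection model) in dying cells.
#' @param n_joint,n_expression_only,n_detection_only planted effect-class
#'   sizes among non-mito genes.
#' @param effect_log2fc planted log2 mean shift (joint and
#'   expression-only classes), random sign per gene.
#' @param joint_detection_delta planted detection logit shift of the
#'   joint class (same sign as its expression shift).
#' @param detection_only_delta planted detection logit shift of the
#'   detection-only class: a subtle frequency modulation, deliberately
#'   smaller than the joint class.
#' @param rin_detection_slope optional nuisance effect of (centered) RIN
#'   on the detection logit; default 0 (off).
#' @param age_range,rin_range per-sample covariate draws (uniform).
#' @param seed integer; fully determines the output.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_samples_per_condition = c(3, 5),
                       condition_labels = c("RRMS", "SPMS"),
                       n_cells_per_sample = 1000,
                       n_genes = 2000,
                       n_mito_genes = 13,
                       cluster_proportions = .default_cluster_proportions,
                       baseline_meanlog = log(0.5),
                       baseline_sdlog = 1.2,
                       cluster_factor_sdlog = 0.3,
                       sample_factor_sdlog = 0.1,
                       nb_size_meanlog = 0,
                       nb_size_sdlog = 0.4,
                       dropout_intercept = 0.5,
                       dropout_slope = 1.3,
                       mito_baseline_mean = 0.3,
                       dying_cell_fraction = 0.02,
                       dying_mito_multiplier = 25,
                       n_joint = 50,
                       n_expression_only = 50,
                       n_detection_only = 50,
                       effect_log2fc = 2,
                       joint_detection_delta = 1,
                       detection_only_delta = 0.15,
                       rin_detection_slope = 0,
                       age_range = c(35, 70),
                       rin_range = c(5, 9),
                       seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(cluster_proportions) - 1) > 1e-8) {
    stop("validation error: cluster_proportions must sum to 1")
  }
  if (is.null(names(cluster_proportions)) || any(cluster_proportions <= 0)) {
    stop("validation error: cluster_proportions must be named and positive")
  }
  stopifnot(
    length(n_samples_per_condition) == 2, all(n_samples_per_condition >= 1),
    length(condition_labels) == 2, n_cells_per_sample >= 1,
    n_genes > n_mito_genes, n_mito_genes >= 0,
    n_joint + n_expression_only + n_detection_only <= n_genes - n_mito_genes,
    dying_cell_fraction >= 0, dying_cell_fraction <= 1,
    dying_mito_multiplier >= 1
  )
  structure(cfg, class = "SimConfig")
}

# zero-truncated NB draws via inverse CDF above the zero mass
.rztnb <- function(n, mu, size) {
  if (n == 0L) return(numeric(0))
  p0 <- stats::pnbinom(0, mu = mu, size = size)
  u <- p0 + (1 - p0) * stats::runif(n)
  stats::qnbinom(pmin(u, 1 - 1e-12), mu = mu, size = size)
}

#' Simulate a multi-sample snRNA-seq dataset with ground truth
#'
#' Draws, under the configured seed: per-sample covariates; per-cell
#' cluster assignments; latent means
#' `baseline x cluster factor x condition effect x sample factor`;
#' detection indicators from the logistic dropout model (shifted by
#' planted detection effects and the optional RIN nuisance, but not by
#' expression effects); zero-truncated NB counts for detected entries; and
#' elevated mitochondrial counts in a small fraction of dying cells.
#' Output is bit-reproducible for a given config.
#'
#' @param config a [sim_config()].
#' @return list with `samples` (list of per-sample [CountMatrix]),
#'   `matrix` (the concatenated [CountMatrix]), `metadata`
#'   (`CellMetadata`), `truth` (GroundTruth data.frame: one row per
#'   gene x cluster with `label` in null / expression_only /
#'   detection_only / joint, `true_log2fc`, `true_detection_delta`),
#'   `dying_cells` (barcodes of planted dying cells) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  set.seed(cfg$seed)

  ng <- cfg$n_genes
  nm <- cfg$n_mito_genes
  mito_idx <- seq_len(nm)
  gene_ids <- c(sprintf("MTSIM%d", seq_len(nm)),
                sprintf("GSIM%04d", seq_len(ng - nm)))
  gene_symbols <- c(sprintf("MT-SIM%d", seq_len(nm)),
                    sprintf("GSIM%04d", seq_len(ng - nm)))

  baseline <- stats::rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
  baseline[mito_idx] <- cfg$mito_baseline_mean
  nb_size <- stats::rlnorm(ng, cfg$nb_size_meanlog, cfg$nb_size_sdlog)

  clusters <- names(cfg$cluster_proportions)
  nc <- length(clusters)
  cluster_factor <- matrix(
    stats::rlnorm(ng * nc, 0, cfg$cluster_factor_sdlog), ng, nc,
    dimnames = list(gene_ids, clusters)
  )
  cluster_factor[mito_idx, ] <- 1

  # planted effects: gene-level labels, effects applied in all clusters
  non_mito <- setdiff(seq_len(ng), mito_idx)
  n_eff <- cfg$n_joint + cfg$n_expression_only + cfg$n_detection_only
  eff_idx <- sample(non_mito, n_eff)
  label <- rep("null", ng)
  label[eff_idx[seq_len(cfg$n_joint)]] <- "joint"
  label[eff_idx[cfg$n_joint + seq_len(cfg$n_expression_only)]] <- "expression_only"
  label[eff_idx[cfg$n_joint + cfg$n_expression_only +
                  seq_len(cfg$n_detection_only)]] <- "detection_only"
  sign_g <- sample(c(-1, 1), ng, replace = TRUE)
  true_log2fc <- ifelse(label %in% c("joint", "expression_only"),
                        sign_g * cfg$effect_log2fc, 0)
  true_det_delta <- ifelse(label == "joint", sign_g * cfg$joint_detection_delta,
                    ifelse(label == "detection_only",
                           sign_g * cfg$detection_only_delta, 0))

  # samples and covariates
  n_s <- cfg$n_samples_per_condition
  sample_ids <- c(paste0(cfg$condition_labels[1L], seq_len(n_s[1L])),
                  paste0(cfg$condition_labels[2L], seq_len(n_s[2L])))
  sample_cond <- rep(cfg$condition_labels, n_s)
  sex <- unlist(lapply(n_s, function(k) rep_len(c("F", "M"), k)))
  sex <- sex[sample(seq_along(sex))]
  age <- stats::runif(length(sample_ids), cfg$age_range[1L], cfg$age_range[2L])
  rin <- stats::runif(length(sample_ids), cfg$rin_range[1L], cfg$rin_range[2L])
  sample_factor <- matrix(
    stats::rlnorm(ng * length(sample_ids), 0, cfg$sample_factor_sdlog),
    ng, length(sample_ids), dimnames = list(gene_ids, sample_ids)
  )

  rin_center <- mean(cfg$rin_range)

  samples <- vector("list", length(sample_ids))
  meta_rows <- vector("list", length(sample_ids))
  dying_all <- character(0)

  for (s in seq_along(sample_ids)) {
    sid <- sample_ids[s]
    is_b <- sample_cond[s] == cfg$condition_labels[2L]
    n_cells <- cfg$n_cells_per_sample
    cell_cluster <- sample(clusters, n_cells, replace = TRUE,
                           prob = cfg$cluster_proportions)
    dying <- stats::runif(n_cells) < cfg$dying_cell_fraction
    barcodes <- sprintf("C%04d-%s", seq_len(n_cells), sid)

    counts <- matrix(0, n_cells, ng)
    for (cl in unique(cell_cluster)) {
      rows <- which(cell_cluster == cl)
      mu <- baseline * cluster_factor[, cl] * sample_factor[, s]
      if (is_b) mu <- mu * 2^true_log2fc
      det_logit <- cfg$dropout_intercept +
        cfg$dropout_slope * log(baseline * cluster_factor[, cl]) +
        cfg$rin_detection_slope * (rin[s] - rin_center)
      if (is_b) det_logit <- det_logit + true_det_delta
      p_det <- stats::plogis(det_logit)

      nr <- length(rows)
      z <- matrix(stats::rbinom(nr * ng, 1L, rep(p_det, each = nr)), nr, ng)
      # dying cells: mito means inflated; detection follows the inflated mean
      mu_mat <- matrix(rep(mu, each = nr), nr, ng)
      dy <- dying[rows]
      if (any(dy) && length(mito_idx)) {
        mu_mat[dy, mito_idx] <- mu_mat[dy, mito_idx] * cfg$dying_mito_multiplier
        p_dy <- stats::plogis(cfg$dropout_intercept + cfg$dropout_slope *
                                log(baseline[mito_idx] *
                                      cluster_factor[mito_idx, cl] *
                                      cfg$dying_mito_multiplier))
        z[dy, mito_idx] <- matrix(
          stats::rbinom(sum(dy) * length(mito_idx), 1L,
                        rep(p_dy, each = sum(dy))),
          sum(dy), length(mito_idx)
        )
      }
      pos <- which(z == 1L)
      if (length(pos)) {
        size_mat <- rep(nb_size, each = nr)[pos]
        cnt <- .rztnb(length(pos), mu_mat[pos], size_mat)
        block <- matrix(0, nr, ng)
        block[pos] <- cnt
        counts[rows, ] <- block
      }
    }

    samples[[s]] <- CountMatrix(
      counts = Matrix::Matrix(counts, sparse = TRUE),
      gene_ids = gene_ids, gene_symbols = gene_symbols,
      barcodes = barcodes, sample_of_cell = sid
    )
    meta_rows[[s]] <- data.frame(
      barcode = barcodes, sample = sid, condition = sample_cond[s],
      cluster = cell_cluster, sex = sex[s], age = age[s], rin = rin[s],
      stringsAsFactors = FALSE
    )
    dying_all <- c(dying_all, barcodes[dying])
  }

  metadata <- as_cell_metadata(do.call(rbind, meta_rows))
  truth <- data.frame(
    gene = rep(gene_ids, times = nc),
    cluster = rep(clusters, each = ng),
    label = rep(label, times = nc),
    true_log2fc = rep(true_log2fc, times = nc),
    true_detection_delta = rep(true_det_delta, times = nc),
    stringsAsFactors = FALSE
  )

  list(
    samples = samples,
    matrix = bind_samples(samples),
    metadata = metadata,
    truth = truth,
    dying_cells = dying_all,
    config = cfg
  )
}

#' Configured per-cluster detection probability
#'
#' The detection probability the generator used for each gene in a given
#' cluster and condition (before sampling noise): the logistic dropout
#' model evaluated at the gene's cluster-level mean, plus any planted
#' detection shift in the non-reference condition. Useful for checking
#' that empirical CDRs converge to their configured values.
#'
#' @param sim a [simulate_dataset()] result.
#' @param cluster cluster name.
#' @param condition condition label.
#' @return named numeric vector of detection probabilities per gene.
#' @export
configured_detection_prob <- function(sim, cluster, condition) {
  cfg <- sim$config
  ng <- cfg$n_genes
  gene_ids <- sim$samples[[1L]]$gene_ids
  # reconstruct deterministic pieces from the truth table and config
  tr <- sim$truth[sim$truth$cluster == cluster, ]
  tr <- tr[match(gene_ids, tr$gene), ]
  set.seed(cfg$seed)
  nm <- cfg$n_mito_genes
  baseline <- stats::rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
  baseline[seq_len(nm)] <- cfg$mito_baseline_mean
  stats::rlnorm(ng, cfg$nb_size_meanlog, cfg$nb_size_sdlog)  # advance RNG
  clusters <- names(cfg$cluster_proportions)
  cf <- matrix(stats::rlnorm(ng * length(clusters), 0, cfg$cluster_factor_sdlog),
               ng, length(clusters), dimnames = list(gene_ids, clusters))
  cf[seq_len(nm), ] <- 1
  det_logit <- cfg$dropout_intercept +
    cfg$dropout_slope * log(baseline * cf[, cluster])
  if (condition == cfg$condition_labels[2L]) {
    det_logit <- det_logit + tr$true_detection_delta
  }
  stats::setNames(stats::plogis(det_logit), gene_ids)
}

#' Write a simulated dataset to disk as pipeline input fixtures
#'
#' Per-sample 10x triplet directories plus `metadata.tsv`, `truth.tsv`
#' and `dying_cells.tsv`, laid out exactly like the real-data interface so
#' [read_10x_mtx()] / [read_metadata()] read it back losslessly.
#'
#' @param sim a [simulate_dataset()] result.
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
write_fixture <- function(sim, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$samples) {
    write_10x_mtx(s, file.path(directory, s$sample_of_cell[1L]))
  }
  write_table(sim$metadata, file.path(directory, "metadata.tsv"))
  write_table(sim$truth, file.path(directory, "truth.tsv"))
  writeLines(sim$dying_cells, file.path(directory, "dying_cells.tsv"))
  invisible(directory)
}
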