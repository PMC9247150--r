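# Independent oracles and small fixture builders shared across tests.

# Benjamini-Hochberg step-up, written from the definition: sort ascending,
# p_(i) * m / i, cumulative minimum from the largest, cap at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i, 1)
    adj[o[i]] <- prev
  }
  adj
}

# Brute-force two-sided rank-sum p: enumerate every assignment of the
# pooled values to group A, with midranks for ties.
wilcox_enum_oracle <- function(values_a, values_b) {
  pooled <- c(values_a, values_b)
  n <- length(pooled)
  nA <- length(values_a)
  r <- rank(pooled)
  combs <- utils::combn(n, nA)
  w_all <- apply(combs, 2L, function(idx) sum(r[idx]))
  w_obs <- sum(r[seq_len(nA)])
  ew <- nA * (n + 1) / 2
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

toy_matrix <- function(counts, symbols = NULL, sample = "S1") {
  counts <- as.matrix(counts)
  ng <- ncol(counts)
  ids <- sprintf("G%03d", seq_len(ng))
  CountMatrix(counts, gene_ids = ids,
              gene_symbols = if (is.null(symbols)) ids else symbols,
              barcodes = sprintf("B%03d", seq_len(nrow(counts))),
              sample_of_cell = sample)
}

toy_metadata <- function(barcodes, sample, condition, cluster,
                         sex = "F", age = 50, rin = 7) {
  data.frame(barcode = barcodes, sample = sample, condition = condition,
             cluster = cluster, sex = sex, age = age, rin = rin,
             stringsAsFactors = FALSE)
}

# down-scaled generator settings for fast unit tests
small_sim <- function(seed = 42, cells = 120, genes = 400, ...) {
  sim_config(n_cells_per_sample = cells, n_genes = genes,
             n_joint = 10, n_expression_only = 10, n_detection_only = 10,
             seed = seed, ...)
}

small_qc <- function() qc_thresholds(min_genes_per_cell = 80)
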