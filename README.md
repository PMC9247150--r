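# vagex

Downstream analysis of multi-sample single-nucleus RNA-seq (snRNA-seq)
comparing two disease conditions — e.g. relapsing-remitting vs.
secondary-progressive multiple sclerosis (RRMS vs. SPMS) — within
annotated cell-type clusters. `vagex` is aimed at analysts who already
have per-sample UMI count matrices and cluster labels and want the
statistical stages after alignment and clustering:

1. **Quality control** (per sample): exclude genes detected in fewer
   than 3 nuclei; retain nuclei expressing at least 300 genes; remove
   dying cells and multiplets as nuclei with mitochondrial count
   fraction > 1% or total transcript count above
   *Q*<sub>0.75</sub> + 1.5 × IQR.
2. **Log normalization**: log<sub>2</sub>(1 + 10⁴ · *c* / total) per
   cell (log2-CP10K), zeros preserved exactly.
3. **Hurdle-model differential expression** per gene within each
   cluster, adjusting for sex, age and RNA integrity number (RIN). The
   two-part model combines a logistic regression of the detection
   indicator 1{*y* > 0} with a Gaussian linear model of log-expression
   among detected cells; the condition effect is tested by a
   likelihood-ratio statistic
   Λ = 2[(ℓ̂₁ᵈ − ℓ̂₀ᵈ) + (ℓ̂₁ᶜ − ℓ̂₀ᶜ)] ~ χ²(df),
   with Benjamini–Hochberg FDR within cluster. DEGs are genes with
   adjusted *p* < 0.05 and fold change > 1.1.
4. **Cell detection rates (CDRs)**: the count matrix is binarized
   (presence/absence); per cluster, each gene's detection rate is
   compared between conditions with a cell-level Wilcoxon rank-sum test
   (exact by enumeration when the smaller group has ≤ 8 cells,
   tie-corrected normal approximation otherwise), with a sample-level
   Student's *t*-test on per-sample CDRs, and genes ranked by CDR ratio
   (SPMS/RRMS by default, top 30).
5. **Vastly altered genes (VAGs)**: the per-cluster intersection of the
   DEG set and the significant-CDR set — genes altered in both
   expression level and expression frequency.

A seeded **synthetic-data generator** reproduces the study design (3 vs.
5 samples, 9 clusters with ~70% oligodendrocytes, zero-inflated
negative-binomial counts, 13 mitochondrial genes, per-sample covariates)
with planted expression-only, detection-only and joint condition
effects, so every stage can be validated against ground truth.

## Worked example

```r
library(vagex)

sim <- simulate_dataset(sim_config(seed = 1))   # 8 samples x 1,000 nuclei
qc  <- apply_qc_samples(sim$matrix)             # per-sample QC cascade
qc$matrix
#> CountMatrix: 7765 cells x 2000 genes, 8 samples, 20915671 total UMIs

x   <- log_normalize(qc$matrix)
dge <- run_dge(x, sim$metadata, "oligodendrocyte")
cdr <- run_cdr(qc$matrix, sim$metadata, "oligodendrocyte")
vag <- extract_vags(dge, cdr)

sum(dge$is_deg); sum(cdr$cdr_fdr < 0.05, na.rm = TRUE); nrow(vag)
#> [1] 110
#> [1] 69
#> [1] 47
venn_counts(dge, cdr)
#>     deg_only     cdr_only intersection
#>           63           22           47

head(vag[, c("gene", "log2fc", "dge_fdr", "cdr_condA", "cdr_condB",
             "direction")], 3)
#>       gene log2fc  dge_fdr cdr_condA cdr_condB  direction
#> 1 GSIM0007 -0.235 2.01e-03     0.660     0.605 up-in-RRMS
#> 2 GSIM0038 -0.837 3.98e-33     0.581     0.325 up-in-RRMS
#> 3 GSIM0074  1.551 2.79e-55     0.815     0.914 up-in-SPMS
```

QC retains 7,765 of 8,000 simulated nuclei (97%), including every
planted dying cell among the removals. In the dominant oligodendrocyte
cluster, 110 of 1,873 tested genes are DEGs, 69 genes have significantly
shifted detection rates, and their intersection gives 47 VAGs —
dominated by the generator's planted joint-effect genes (45 of the 50
planted recovered; a single null gene leaks in, a false-VAG rate of
0.05%). `cdr_ratio_rank(cdr,
"B>A", k = 30)` returns the top-30 genes by detection-rate ratio, the
ranking used to scan pathway panels for frequency shifts.

For whole-pipeline runs (all clusters, TSV/JSON outputs plus a run
manifest) use `run_all(pipeline_config(...), out_dir = "...")`, or the
command-line wrapper:

```sh
Rscript inst/scripts/vagex-pipeline.R simulate --out data --seed 1
Rscript inst/scripts/vagex-pipeline.R run-all --input data --out results
```

## Package layout

- `R/` — implementation: I/O (`read_10x_mtx`, `read_metadata`,
  `write_table`), QC (`apply_qc`), normalization (`log_normalize`),
  hurdle DGE (`fit_hurdle`, `run_dge`), CDR statistics
  (`wilcoxon_cdr_test`, `ttest_cdr`, `run_cdr`, `cdr_ratio_rank`), VAG
  extraction (`extract_vags`, `venn_counts`), the generator
  (`simulate_dataset`, `write_fixture`) and orchestration (`run_all`).
- `vignettes/methods.Rmd` — the statistical model, its assumptions,
  default parameters and known limitations.
- `tests/testthat/` — unit, property and end-to-end tests with
  independent oracles (closed forms, exhaustive enumeration, reference
  implementations).
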