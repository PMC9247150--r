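---
title: "Methods: QC, hurdle differential expression, detection-rate statistics and VAG extraction"
author: "vagex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC, hurdle differential expression, detection-rate statistics and VAG extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vagex` implements the downstream statistical stages of a two-condition
single-nucleus RNA-seq comparison within annotated cell clusters. This
vignette documents the models, their assumptions, the defaults and why
they were chosen, the numerical conventions, and what the synthetic
validation does and does not establish about real data.

## Quality control

QC is applied strictly **per sample** — every threshold and quantile is
computed within one sample's matrix, never on the pooled data — in this
order:

1. *Gene filter*: keep genes detected (count > 0) in at least
   `min_cells_per_gene = 3` nuclei.
2. *Nucleus complexity filter*: keep nuclei expressing at least
   `min_genes_per_cell = 300` genes. The bound is inclusive ("at
   least"), while the next two rules are strict ("exceeding").
3. *Dying cells and multiplets*: remove nuclei with mitochondrial count
   fraction > `max_mito_fraction = 0.01` **or** total transcript count
   above Q(0.75) + 1.5 × IQR of the per-nucleus totals, with the
   quantiles computed on the nuclei that survived steps 1–2. A nucleus
   failing both rules is attributed to the mitochondrial rule in the QC
   report (first-triggering attribution), so the per-rule removals
   always sum to the total.

Whether the transcript-count quantile should be computed before or
after the mitochondrial exclusion is genuinely open; we compute both
rules simultaneously on the post-complexity-filter cells and record the
order in the report, so the choice is auditable. Mitochondrial genes
are identified by the case-insensitive gene-symbol prefix `"MT-"`
(human nomenclature). The quantile convention is linear interpolation
between order statistics (R type 7); it is configurable because the
rule's outcome near ties depends on it. After per-sample QC, samples
are concatenated over the **union** of retained genes (genes absent in
a sample are zero-filled) so that downstream stages operate on a common
gene space; barcodes are suffixed `-<sampleID>` on collision.

Note one subtlety: re-running QC on an already filtered sample can drop
further borderline genes, because gene detection counts are
re-evaluated on the reduced cell set. The retained cell set itself is
stable when the outlier multiplier is large.

## Normalization

The hurdle model's continuous part consumes
`log2(1 + scale_factor * count / total)` with `scale_factor = 10000`
(log2-CP10K). Zeros map exactly to zero, preserving the detection axis.
Regularized negative-binomial residual normalization is used by some
pipelines for integration and clustering; those stages sit upstream of
this package's scope, and the two-part model below only requires a
monotone per-cell-depth-corrected log scale, for which log2-CP10K is
the standard choice. The scale factor is configurable.

## The hurdle model

For one gene in one cluster, let \(y_i\) be the log-expression of cell
\(i\) and \(z_i = 1\{y_i > 0\}\). With design matrix \(X\) containing
intercept, condition, sex, age and RIN:

- **Discrete part**: logistic regression \(z_i \sim X\beta_d\),
  capturing shifts in expression *frequency*;
- **Continuous part**: Gaussian linear model \(y_i \sim X\beta_c\) on
  the cells with \(z_i = 1\), capturing shifts in expression *level*
  among expressing cells.

The condition term is dropped from both parts to form the null fits,
and the likelihood-ratio statistic sums both contributions:
\(\Lambda = 2[(\hat\ell_1^d - \hat\ell_0^d) + (\hat\ell_1^c -
\hat\ell_0^c)] \sim \chi^2_{df}\), where \(df\) counts the estimable
condition coefficients across the two parts (2 for a two-level
condition with both parts estimable).

Numerical conventions, in decreasing order of how often they matter:

- *Degenerate parts.* If every cell (or no cell) detects the gene, the
  discrete part has no information: it contributes 0 to \(\Lambda\) and
  nothing to \(df\). Symmetrically for the continuous part when fewer
  than 2 cells are detected, when the condition is constant among
  detected cells, or when the model is saturated. On all-detected
  genes, the hurdle p therefore equals the Gaussian-only LRT p exactly.
  If the detected values have zero variance the continuous fit is
  perfect under both hypotheses; the contribution is 0 with the
  condition df retained, so a constant, fully detected gene gives
  p = 1 rather than an artificial NA.
- *Separation.* If the unpenalized logistic IRLS fails to converge in
  100 iterations (complete separation is common for all-or-nothing
  detection), both the full and null discrete fits are redone with a
  ridge penalty of 1e-4 on the coefficients, and the fit's `converged`
  flag is lowered. The reported log-likelihood is the unpenalized
  binomial likelihood at the stabilized estimate.
- *Variance.* The Gaussian log-likelihood is evaluated at the MLE
  variance (RSS/n); there is no empirical-Bayes shrinkage across genes.
  Shrinkage mainly matters for very small clusters, where the
  per-condition cell floor (below) already guards the fit.
- *Covariates.* Sex is treatment-coded; age and RIN are z-scored
  internally for conditioning, which also makes the LRT exactly
  invariant to affine rescaling of these covariates. Constant or
  collinear columns are dropped before fitting (a design with as many
  sample-level parameters as samples is reported degenerate rather than
  silently fit).

The **fold change** is estimated as the difference of group means of
the log2-normalized values *with zeros included*, second condition
level minus the first (reference; RRMS under the default labels). This
convention is independent of covariate coding, matches how single-cell
fold changes are commonly reported, and responds to both frequency and
level shifts — which is what the DEG definition intends. A gene is a
**DEG** when its within-cluster BH-adjusted p is below
`fdr_threshold = 0.05` and \(|\text{log2FC}|\) exceeds the fold-change
cut. The cut `fc_threshold = 1.1` is interpreted on the ratio scale by
default (\(|\text{log2FC}| > \log_2 1.1 \approx 0.138\), the usual
"fold change > 1.1" reporting convention); `fc_scale = "log2"` switches
to \(|\text{log2FC}| > 1.1\) for the stricter literal reading. Both
regulation directions are kept.

Two testing guards are deliberate additions, both configurable: a
cluster is only tested with at least `min_cells_per_condition = 10`
cells per condition, and a gene is only tested when detected in at
least `min_detection_frac = 5%` of the cluster's cells in one
condition (set 0 to disable). Untested genes are flagged, not dropped.
Multiple testing is corrected **within each cluster** over the tested
genes, matching per-cluster DEG reporting. An optional cellular
detection-rate covariate (the per-cell fraction of detected genes) is
not included by default; the adjusted covariates are sex, age and RIN
only.

## Detection-rate statistics

The count matrix is binarized (1 iff count > 0). For each gene within a
cluster the **cell detection rate** per group is the mean of the binary
column over that group's cells, so the per-condition CDR is exactly the
cell-count-weighted mean of the per-sample CDRs.

Two tests are offered at different units of analysis:

- **Cell-level Wilcoxon rank-sum** on the binary values, the test used
  for VAG eligibility. Because binary data are maximally tied, the exact
  distribution of the rank-sum statistic given the total number of ones
  is induced by a hypergeometric draw, and for min(group size) ≤ 8 the
  two-sided p is computed by exact enumeration over that distribution.
  For larger groups the tie-corrected normal approximation with
  continuity correction is used (it matches reference rank-sum
  implementations to well below 1e-8). In the balanced all-or-nothing
  case the exact p coincides with Fisher's exact test on the 2×2
  detection table.
- **Sample-level Student's t-test** (pooled variance; Welch by option)
  on the per-sample CDR proportions, requiring ≥ 2 samples per
  condition — the design-aware complement that respects sample as the
  experimental unit. Proportions are not transformed (no arcsine or
  logit) before the t-test; with 3–5 samples per group a transform
  changes little, and the untransformed test is what the headline
  per-sample comparison reports. This is recorded as a limitation.
  When both groups have zero variance the test is degenerate: p = 1
  for equal means, otherwise the smallest representable double with a
  `degenerate` flag.

The **CDR ratio** is condition B over condition A (SPMS/RRMS by
default). `cdr_ratio_rank()` partitions genes by direction, ranks by
\(|\log \text{ratio}|\) descending (ties broken by gene id), and
returns the top `k = 30`; genes with a zero denominator rank first in
their direction and carry a flag.

"Significant CDR" for VAG eligibility means within-cluster BH-adjusted
cell-level Wilcoxon p below 0.05 — mirroring the DEG FDR criterion,
since no separate threshold is canonical; the cutoff is a parameter and
is echoed in output manifests.

## Vastly altered genes

A **VAG** is a gene that is simultaneously a DEG and significant-CDR
within the same cluster — altered in both level and frequency.
`extract_vags()` intersects by gene id (never by symbol, which may
collide), joins the evidence columns from both tables, and orders rows
by gene id. Genes whose log2FC sign disagrees with the sign of the CDR
difference are flagged `discordant` but retained, since discordance is
itself informative (e.g. fewer cells expressing more per cell). There
is no cross-cluster pooling.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the analysis assumes:
3 vs. 5 samples per condition, 1,000 nuclei per sample by default
(5,000 is the full study-scale option), 2,000 genes of which 13 are
mitochondrial (`MT-SIM1..13`, exercising the prefix rule), and 9
clusters with a dominant oligodendrocyte cluster at 70%. Counts follow
a zero-inflated negative binomial: gene baseline means are log-normal
(meanlog log 0.5, sdlog 1.2), per-gene NB size is log-normal (meanlog
0, sdlog 0.4), gene-by-cluster factors are log-normal (sdlog 0.3), and
detection follows a logistic model in the log cluster-level mean
(intercept 0.5, slope 1.3), giving a median of roughly 850 expressed
genes and 2,700 UMIs per nucleus — comfortably above the 300-gene QC
floor, as in the deeply sequenced tissue the design mimics. Sample
covariates: age ~ U(35, 70), RIN ~ U(5, 9), sex balanced within
condition; per-sample log-normal factors (sdlog 0.1) induce
within-condition sample correlation in expression magnitude. An
optional RIN-on-detection nuisance slope (default 0) exists to stress
covariate adjustment. Two percent of cells are "dying": their
mitochondrial means are multiplied by 25, which lands their
mitochondrial fraction around 4–5% versus ~0.2–0.4% for healthy cells,
so the 1% QC rule separates them cleanly.

A deliberate design decision is that the **detection probability is
computed from the cluster-level latent mean and is decoupled from both
the planted expression shifts and the per-sample magnitude factors**.
Detection changes only through explicit detection deltas. This makes
the three planted effect classes mean what they say — expression-only
genes change level but not frequency, detection-only genes change
frequency but not conditional level — which is precisely the structure
the DEG/CDR/VAG logic is supposed to distinguish, and it makes the
configured per-cluster detection probability an exact target for the
empirical CDR (binomial sampling error only). It also means the
generator does not reproduce the mean–dropout coupling of real
droplet data *within* a condition contrast; conclusions about the
pipeline's behavior under correlated mean/detection shifts rest on the
joint class.

Planted effects (defaults, chosen once as the study conditions): 50
joint genes (log2 mean shift ±2 with a sign-matched detection logit
shift ±1.0), 50 expression-only genes (±2, no detection shift), 50
detection-only genes (detection logit shift ±0.15 — a subtle frequency
modulation, an order of magnitude below the joint class, reflecting
that pure-frequency effects without any level change are typically
weak). Signs are random per gene. Effects apply in all clusters;
ground-truth labels partition genes.

What passing the synthetic validation shows — and what it does not.
Recovery of planted joint effects as VAGs (recall ≥ 0.9, Jaccard ≥ 0.8
against truth, null false-VAG rate at the per-mille level) demonstrates
that the pipeline's thresholds and intersection logic identify
jointly-altered genes under the assumed ZINB structure at the default
depth. It does not certify behavior under ambient RNA, doublets beyond
high-count cells, batch effects, gene–gene correlation, or cell-type
misannotation, none of which the generator models. Also note that
planted fold changes on very weakly expressed genes are intrinsically
invisible: a zero-truncated count that is almost always 1 carries no
magnitude information, so expression-only effects are only recoverable
where the gene is detected often enough (empirically, maximum CDR ≳
0.4 at default depth).

A second caveat worth stating: the shared per-sample factors make
cell-level p-values mildly anti-conservative under the null
(pseudoreplication), which is a property of cell-level testing in
multi-sample designs generally, not of this implementation — the
package's sample-level t-test is the design-aware alternative. The
hurdle test's own calibration, measured with sample effects off (2,000
null ZINB genes, 200 cells), is accurate: type-I error ≈ 0.05 at
α = 0.05 and a uniform p-value distribution.

## Problem sizes and determinism

The validation suite runs the generator at its default size (8 × 1,000
cells × 2,000 genes) for recovery scoring, 2,000 null genes × 200 cells
for calibration, and down-scaled configurations (120–150 cells/sample,
350–400 genes, with the complexity floor scaled to 80 genes
accordingly) for structural and determinism checks — sizes chosen so
each property is measured with adequate precision while the whole suite
stays quick on a single core. Every random stage derives from one seed:
a config plus seed reproduces all output tables byte for byte, and the
run manifest echoes every threshold so the analysis decisions above are
auditable in each result set.
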