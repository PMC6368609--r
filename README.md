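# innateness

Human innate T cells (iNKT, MAIT, γδ T subsets) sit functionally between
classical adaptive T cells and natural killer cells, and their
transcriptomes order these populations along a continuous "innateness
gradient": CD4 T = 1, CD8 T = 2, MAIT = 3, iNKT = 4, Vδ1 = 5, Vδ2 = 6,
NK = 7. This package implements, as tested reusable components, the
computational procedures for quantifying that gradient:

* **Gradient association** — per gene, a linear mixed model
  `log2(tpm+1) ~ β·rank + (1 | donor)` fit by ML with a 1-df
  likelihood-ratio test and Bonferroni calling (`fit_gradient_bulk()`);
  for single cells, a linear model with log-UMI, percent-mito, and donor
  covariates and nonzero-cell filters (`fit_gradient_sc()`,
  `de_one_vs_rest()`).
* **Innateness score** — PC1 loadings of the centered/scaled
  variable-gene reference matrix; any sample or cell is scored as
  `orientation · Σ_g loading_g · z_g`, a projection onto the reference
  PC1 (`fit_score_model()`, `project_score()`).
* **Hashing demultiplexing** — droplet QC with the three antibody
  exclusion criteria (≥ 10 total UMIs; second ≤ 10% of top;
  top ≥ 75% of total) applied per barcode set, mRNA QC (> 500 genes,
  < 20% mito), and the < 5-reads UMI filter (`demux()`,
  `antibody_qc()`, `mrna_qc()`, `filter_umis_by_reads()`).
* **Enrichment** — exact minimal hypergeometric test on β-ranked genes
  (`mhg_test()`, `go_enrichment()`), pathway F-statistic tests with
  expression-matched nulls (`pathway_f_test()`,
  `matched_null_f_test()`), strand-aware peak-to-gene target assignment
  and logistic target enrichment (`assign_peak_targets()`,
  `target_enrichment_logistic()`).
* **Metrics** — individual innateness metric (rank-weighted ITC
  proportions), cytokine/chemokine gene-set mass, CFSE division index.
* **Synthetic data** — generators for bulk (6 donors × 7 types × 2
  replicates), hashed droplet single-cell, and cohort data with known
  ground truth, so every stage is testable without downloads
  (`simulate_bulk()`, `simulate_sc()`, `simulate_cohort()`).

See `vignettes/innateness-methods.Rmd` for the models, assumptions, and
design choices.

## Worked example

The numbered scripts under `analysis/` run the full workflow on
synthetic data (`Rscript analysis/01_simulate.R`, then `02`…`06`).
A condensed version:

```r
library(innateness)

sim  <- simulate_bulk(bulk_sim_design(seed = 1))   # 2000 genes, 84 samples
mlog <- log_transform_bulk(sim$matrix)
fit  <- fit_gradient_bulk(quantile_normalize(mlog))
cor(fit$beta, sim$truth$beta_true)                 # 0.926
sum(fit$significant)                               # 149 genes, 148 true positives

model <- fit_score_model(mlog, select_variable_genes_sd(mlog, 0.5))
proj  <- project_score(model, mlog)
tapply(proj$score, rank_cell_types(mlog$meta$cell_type), mean)
#  -14.60  -9.67  -4.90  -0.24  5.03  10.10  14.28   (ranks 1..7)
```

The fitted β per gene tracks the planted effect sizes, the Bonferroni
calls are specific, and the mean innateness score increases strictly
with the cell type's gradient rank — the score axis recovers the
planted ordering. `analysis/04_demux.R` retains 839 of 1050 simulated
droplets, assigns 100% of retained singlets to their true (cell type,
donor), and excludes all 63 planted doublets; `analysis/05_enrichment.R`
finds the planted innate gene set at mHG p = 3e−42 in the innateness
direction (p = 1 in the adaptive direction) while the best random set
sits at p = 0.13.

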