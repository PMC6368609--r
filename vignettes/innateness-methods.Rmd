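---
title: "Quantifying lymphocyte innateness: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lymphocyte innateness: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innateness)
```

## The innateness gradient

Human lymphocyte populations can be ordered along a functional axis from
prototypically adaptive to prototypically innate: CD4 T = 1, CD8 T = 2,
MAIT = 3, iNKT = 4, Vδ1 = 5, Vδ2 = 6, NK = 7
(`default_cell_type_ranks()`). This package quantifies how strongly each
gene's expression tracks that rank order, builds a transferable
per-sample/per-cell "innateness score" from the first principal
component of the reference expression matrix, and provides the
supporting machinery: droplet demultiplexing for hashed single-cell
runs, enrichment statistics, and ancillary metrics.

### Bulk gradient model

For bulk (low-input) RNA-seq with repeated sampling of donors, the
per-gene model is a linear mixed model on log2(tpm + 1) expression:

$$y_{gs} = \alpha_g + \beta_g \cdot \mathrm{rank}_s + u_{g,d(s)} +
\varepsilon_{gs}, \qquad u_{g,d} \sim N(0, \sigma^2_{donor}),\;
\varepsilon \sim N(0, \sigma^2)$$

β (the "innateness level") is the change in log2 expression per unit
rank. The gradient effect is tested with a likelihood-ratio test
against the model without the rank term, with p-values from χ²(1), and
genes are called significant at the Bonferroni threshold α / (number of
genes tested).

Two estimation choices matter here:

* **ML, not REML.** REML likelihoods are not comparable between models
  with different fixed effects, so both nested fits are maximum
  likelihood. This is required for the LRT to be valid.
* **Boundary fits.** When the donor variance estimate hits zero the
  mixed fit is singular; both nested models are then refit by ordinary
  least squares and the gene is flagged (`singular`). This preserves
  the 1-df LRT in the degenerate case. No boundary-correction halving
  of the χ² p-value is applied — χ²(1) is the reference distribution
  reported, matching standard `anova()` behavior for nested fits; a
  user wanting the halved p can apply it downstream since the LRT
  statistic is returned.

For single-cell data the same structure is fit as an ordinary linear
model per gene with technical covariates — log total UMIs, percent
mitochondrial UMIs (0–100 scale), and a donor indicator — again tested
by a 1-df LRT. Genes with nonzero expression in fewer than 100 cells
(gradient association) or 60 cells (one-vs-rest subset comparisons) are
skipped, and the Bonferroni denominator counts only genes actually
tested.

### The innateness score

`fit_score_model()` selects variable genes, centers and scales each
across the reference samples, and takes the first principal component.
The score of any query sample is the loading-weighted sum of its scaled
expression over the model genes — a projection onto the reference PC1.
Choices:

* **Orientation.** The PCA sign is arbitrary; it is fixed so the mean
  score of the highest-rank cell type exceeds that of the lowest-rank
  type (higher score = more innate).
* **Query scaling.** By default, z-scores are computed within the query
  dataset (each gene scaled by its own query mean/s.d.), because
  queries come from other platforms (microarray, imputed single-cell)
  where reference centering is not transferable. Using the stored
  reference center/scale is available via `scaling = "reference"`.
* **Partial gene overlap.** Model genes absent from the query
  contribute zero (the mean); coverage is reported and a warning fires
  below 50%. Scores are not renormalized by gene count — coverage is
  the honest report of comparability.
* **Scaling for the bulk PCA.** Genes are centered *and* scaled (unit
  sample s.d.). Scaling only for the single-cell PCA would leave the
  bulk score dominated by high-variance genes; unifying on scaled input
  makes the score a plain dot product with z-scores in both uses.

The s.d. convention throughout (variable-gene selection, scaling) is
the sample s.d. with an n−1 denominator, the `stats::sd()` convention.

### Hashing demultiplexing

Droplets pass three independent gates: mRNA QC (more than 500 unique
genes and less than 20% mitochondrial UMIs), and per barcode set —
cell-type antibodies and donor antibodies separately — the three
exclusion criteria: at least 10 total antibody UMIs; second-most
abundant antibody at most 10% of the most abundant; most abundant at
least 75% of the total. Antibody UMIs supported by fewer than 5 reads
are discarded before counting. Boundary semantics are taken literally
from the criteria's wording: equality always **passes** (total = 10
keeps, second = exactly 10% keeps, top = exactly 75% keeps). This is
worth stating prominently because off-by-one conventions differ between
demultiplexing tools. Retained droplets are assigned the top barcode of
each set; a tie at the top is impossible for a passing droplet (the 10%
criterion forces strict ordering) and is asserted. Droplets failing the
10% criterion on the cell-type set are annotated multiplet-suspect —
an annotation, not a doublet call. Mitochondrial genes are recognized
by a configurable id prefix (`MT-` by default).

### Enrichment

**Minimal hypergeometric (mHG).** Genes are ranked by β (descending for
innateness, ascending for adaptiveness) and the statistic is the
minimum hypergeometric tail over all list prefixes. Because the minimum
optimizes over cutoffs, the exact p-value is computed by a dynamic
program over the (prefix, hits) lattice: a random placement of the set
is a lattice path with hypergeometric step probabilities, and p is one
minus the probability of reaching the end without entering a cell whose
tail probability is at or below the observed minimum. The DP runs in
O(NK) with plain doubles (probabilities, not path counts, so nothing
overflows); cells tie with the minimum under a 1e−12 relative
tolerance. Tests verify exact agreement with exhaustive enumeration for
all N ≤ 12. No multiple-testing correction is applied across sets by
default; raw enrichment p-values are reported.

**Expression-matched pathway null.** The per-gene one-way ANOVA F
statistic across cell types is compared between a pathway and a matched
null: for each pathway gene, 30 random non-pathway genes whose mean
expression lies within 0.10 × s.d. of the per-gene mean-expression
distribution. This reading — tolerance proportional to the s.d. of
mean expression over all genes — is the one interpretation of
"within 10% of the standard deviation" that yields a well-defined
per-gene pool; it is isolated behind the `tolerance` argument so other
readings are pluggable. Matches are sampled without replacement within
a pool; pools smaller than 30 are sampled with replacement and flagged,
and an empty pool (a gene at the expression extremes) is relaxed to the
single nearest-expression candidate and flagged. The per-gene samples
are pooled without deduplication, so each pathway gene contributes
equal weight to the null. The comparison is a one-sided Wilcoxon test.

**Peak targets.** Coordinates are 0-based half-open throughout (the BED
convention). The body rule pads the gene span by 2 kb on both sides —
the union of the gene body and a ±2 kb TSS window, since the TSS sits
at one end of the span. The promoter rule is strand-aware: 2 kb
upstream to 1 kb downstream of the TSS. Target enrichment in a DE
comparison is a logistic regression of target status on β with a Wald
test; perfect separation falls back to a small L2 penalty on the slope
(λ = 1e−3) with a warning, since the unpenalized MLE diverges.

### Ancillary metrics

The **individual innateness metric** is the sum over measured ITC
populations of (proportion of T cells) × (gradient rank). The adaptive
remainder of the T-cell pool is excluded by default; including it at a
chosen rank (e.g. 1.5 for a CD4/CD8 mixture) is an option, since with
it the metric becomes a strictly increasing affine transform and the
default keeps the metric interpretable as "rank-weighted ITC burden".
The **division index** formula uses its printed coefficients verbatim,
including 2.67 and 8 for the pooled ≥ 3-divisions class; no attempt is
made to "correct" them to idealized geometric weights. **Gene-set
mass** is summed on the linear tpm scale, matching how aggregate
cytokine/chemokine expression is plotted.

## What the synthetic data emulates

The generators produce data with the statistical structure the
estimators assume, so parameter recovery is a fair, fully specified
test.

**Bulk** (`bulk_sim_design()`): 6 donors × 7 cell types × 2 replicates
(84 samples), 2000 genes, 10% of them with nonzero β drawn uniformly
from ±0.5 log2 units per rank step. The generative model is exactly the
additive Gaussian model the LMM fits: donor random intercepts
(s.d. 0.3) plus residual noise (s.d. 0.4) on the log2(tpm+1) scale,
back-transformed to tpm. The noise levels are in the range typical of
low-input RNA-seq replicates on the log2 scale; β up to 0.5 per rank
step spans the magnitudes seen for strongly gradient-associated genes.
Baselines are drawn uniformly from log2 3–8: the generator emulates the
*post-filter* analysis set (genes expressed at log2(tpm+1) > 2 in ≥ 10
samples), and baselines below that would also push rank-shifted values
under the tpm = 0 floor, censoring data the model class does not
represent.

A note on quantile normalization in recovery experiments: on real data
QN removes technical distribution differences between samples. The
simulation has none, so QN is the identity in expectation — but at 2000
genes its finite-sample quantile mapping perceptibly distorts the 10%
of genes whose distributions genuinely shift with rank (mean recovery r
drops from ≈ 0.97 to ≈ 0.93, and the effect does not vanish as noise
→ 0). Parameter-recovery checks therefore fit the model on
log2(tpm+1) directly, which measures the estimator; QN's own
post-conditions (equal sorted columns, idempotence, rank preservation)
are verified separately. The full published pipeline including QN is
exercised end-to-end in `analysis/02_gradient.R`.

**Single cell** (`sc_sim_design()`): 150 droplets per population from 2
donors, log-normal depth around 2500 UMIs, Beta(2, 38) mitochondrial
fractions (mean 5%, a tail above 20%), 5% doublets, and Poisson(100)
antibody UMIs per barcode set split multinomially with 5% ambient mass
on wrong barcodes. Doublets split cell-type antibody mass 50/50 between
two distinct types while the donor barcode stays single (populations
were pooled within donor before mixing). Counts are Poisson given
per-gene rates; overdispersion, dropout curves, batch effects, and
read-level simulation are deliberately not modeled — passing tests show
the demultiplexer and estimators behave correctly under their assumed
model, not that they are robust to every real-data pathology.
Sequencing depth effects are not modeled either; the generators work
directly on the expression scale.

**Cohort** (`simulate_cohort()`): log-normal percentages calibrated to
long-run means MAIT 2.4%, iNKT 0.09%, Vδ1 1.25%, Vδ2 4.7% of T cells,
ages uniform 20–58, and a −0.03/year effect on the log MAIT and Vδ2
percentages (with an analytic correction so the long-run means stay at
their targets despite the age effect). Values below 0.01 are floored at
0.01, the convention for undetectable iNKT measurements before log
transformation. Percentages are drawn on the log scale because
cohort-trait regressions run on log percentages.

All generators restore the global RNG state on exit and are
bit-reproducible under their `seed` argument.

## Numerical choices and degenerate inputs

* Quantile-normalization ties receive the mean of the reference values
  across their tied ranks; the reference is the row-wise mean of the
  sorted columns.
* CV ties in variable-gene selection break lexicographically by gene
  id, for determinism.
* Zero-variance genes are dropped (with a warning) before scaling and
  PCA; zero rows in L2 normalization stay zero and are flagged.
* An unbounded ANOVA F (zero within-group mean square) is returned as a
  large finite value (1e300) with an `"unbounded"` attribute rather
  than `Inf`, so downstream sorting and tabulation stay well-defined.
* The LRT statistic is clamped at 0 against floating-point negatives.
* Sign concordance between effect-size vectors excludes exact zeros.

## Problem sizes

The test-suite and acceptance runs use the generator defaults above:
2000-gene bulk recovery plus a 2000-gene all-null run for type-I error
(84 samples each), 10,000 randomized droplets for the demultiplexing
oracle comparison, 200 random mHG configurations at N ≤ 12 against
exhaustive enumeration, and 500 seeded repeats of the matched-null
calibration over an 800-gene universe. These sizes give the Monte-Carlo
estimates (type-I rate, KS uniformity) standard errors comfortably
inside the bands they are checked against.

## Known limitations

* The bulk LMM fits one random intercept (donor); crossed or nested
  random effects (e.g. batch within donor) are out of scope, as is
  moderated/shrinkage differential expression.
* The mHG dynamic program is exact but O(NK); for very large lists a
  permutation approximation may be preferable (the statistic itself is
  O(N)).
* The matched-null tolerance reading is one defensible interpretation;
  alternatives plug in via the `tolerance` argument.
* The demultiplexer is rule-based by design; model-based HTO callers
  (Gaussian-mixture demultiplexing) are out of scope.
* Scores projected across platforms depend on within-query scaling
  being meaningful; datasets with few samples or heavy imputation will
  have unstable per-gene s.d. estimates.
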