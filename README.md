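# orgretain

Intestinal organoids are widely used as an in vitro stand-in for the gut
epithelium, but how much of the tissue's biology actually survives two weeks
of culture? `orgretain` implements a complete, testable pipeline for the
question as posed by paired crypt/organoid bulk RNA-seq studies: crypts are
isolated from the oral (duodenum), intermediate (jejunum) and aboral (ileum)
small intestine of male and female, young and old mice; half of each sample
is sequenced directly (in vivo) and half cultured into organoids and then
sequenced (in vitro), giving a 2 × 3 × 2 × 2 factorial with 4 replicates —
96 bulk samples.

The package is aimed at computational biologists who want to (a) reproduce
this style of analysis end to end on synthetic data with known ground truth,
and (b) reuse the individual stages — variance decomposition, cell-type
deconvolution, gene-set enrichment, DEG-matrix effect sizes — on their own
count matrices.

## What it computes

**Variance decomposition.** Normalized counts (median-of-ratios size
factors, as in the Var = μ + αμ² negative-binomial parameterization used
throughout) are filtered to highly-variable, robustly expressed genes
(IQR of log2 counts > 1.5; mean normalized count > 10 in more than 3 of the
24 condition groups), then decomposed by PCA on unit-scaled genes. Each
component is tested against each design factor (Welch t for two levels,
one-way ANOVA for three), and highly contributing genes are selected by the
fixed cutoff log2(contribution %) ≥ −3.32 (≈ 0.1%).

**Cell-type reference and deconvolution.** Synthetic labeled single-cell
data (8 epithelial types: stem, TA, late enterocyte progenitor, enterocyte,
enteroendocrine, goblet, Paneth, tuft) are normalized to the median per-cell
total, log10-transformed, clustered by k-means (nstart = 10) on the top
principal components, typed by canonical markers, and reduced to a
marker × cell-type signature matrix. Bulk samples are then expressed as
non-negative mixtures of the signature columns (NNLS, renormalized to the
simplex), validated on simulated mixtures by pooled Pearson R².

**Enrichment.** A weighted running-sum enrichment score: walking down the
ranked gene list, set members increment the sum by |r|^p (normalized by the
total hit weight) and misses decrement by 1/(N − |S|); the score is the
signed maximum deviation, a weighted Kolmogorov–Smirnov-like statistic.
P-values come from gene-label permutations (plus-one corrected) with BH
adjustment. Directional Z-score summaries (scaled expression × ±1 per gene,
averaged per sample and group) cover signed pathway sets.

**Effect sizes.** Per-contrast negative-binomial Wald tests produce DEG
tables; log2 fold changes of significant genes (zeros elsewhere) form a
genes × contrasts DEG matrix. The in vitro retention of each in vivo feature
is the adjusted R² = 1 − (1 − R²)(n − 1)/(n − k − 1) of a linear model
predicting the in vivo log2FC vector from the matching in vitro vector(s),
with an F-test for model quality; the same machinery quantifies how much
compartment and gender modify the aging response.

All randomness flows from one root seed through named substreams, so every
stage — and the whole run — is reproducible hash-for-hash.

## Worked example

```r
library(orgretain)

run <- run_study(sim_config(seed = 1))
run
#> orgretain pipeline run (seed 1)
#>   PC1 variance fraction: 52.8%
#>   DEG contrasts: 19
#>   deconvolution R2 (cv 5%): 0.999
#>   report hash: 0fd2efc60efe3ceb442e3f42ba8f1d78

glance(run$pca)
#> # A tibble: 96 × 2
#>   component variance_fraction
#> 1 PC1                 0.528
#> 2 PC2                 0.170
#> 3 PC3                 0.100
#> 4 PC4                 0.0730
```

PC1 carries the culture axis (the generator plants the in vivo/in vitro
difference at 60% of the signal variance; after filtering and counting
noise, PC1 explains 52.8% of the total), PC2 the compartment gradient, PC3
and PC4 gender and age. Stem and TA markers are enriched at the organoid
end of the crypt-vs-organoid ranking, differentiated lineages at the crypt
end:

```r
run$gsea[, 1:5]
#> # A tibble: 8 × 5
#>   set                       size     es  pvalue   padj
#> 1 Stem                        30  0.791 0.00200 0.0160
#> 2 TA                          30  0.713 0.00799 0.0213
#> 3 LateEnterocyteProgenitor    30 -0.756 0.00400 0.0160
#> 4 Enterocyte                  30 -0.537 0.146   0.167
#> ...
```

Feature retention: with the default generator (all biology effects fully
shared between crypts and organoids) each in vivo feature is almost fully
recovered from its in vitro counterpart; lowering a factor's
`share_in_vitro` lowers its adjusted R² accordingly.

```r
run$effects$retention[, c("feature", "model", "adj_r2", "n_genes")]
#> # A tibble: 6 × 4
#>   feature     model    adj_r2 n_genes
#> 1 compartment simple    0.977     604
#> 2 compartment combined  0.977     604
#> 3 gender      simple    0.972     604
#> 4 gender      combined  0.972     604
#> 5 aging       simple    0.965     604
#> 6 aging       combined  0.965     604
```

`report_summary(run)` prints the six headline tables (variance fractions,
PC–factor associations, DEG counts, composition tests, enrichment, effect
sizes); `autoplot(run$pca, run$sim$samples)`, `plot_composition()`,
`plot_running_sum()` and `plot_retention()` draw the corresponding figures.

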