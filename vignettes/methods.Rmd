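---
title: "Models and methods behind orgretain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orgretain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orgretain` quantifies how much of the in vivo biology of the intestinal
epithelium — its position along the gut, the animal's sex, its age — is
still visible in the transcriptome after crypts are cultured into
organoids. This vignette documents the statistical models, the synthetic
data that exercises them, and the numerical and design choices made where
several defensible options existed.

## The synthetic study

### Design

The generator reproduces the factorial structure of a paired
crypt/organoid experiment: `sample_type` (crypt, organoid) ×
`compartment` (oral, intermediate, aboral) × `gender` (male, female) ×
`age` (young, old), with 4 replicates — 96 bulk samples. The first level of
every factor is its reference for differential expression; the compartment
contrast is always reported as aboral relative to oral.

### Count model

Counts are negative binomial with mean `mu` and dispersion `alpha`,
`Var = mu + alpha * mu^2`. Per-gene dispersions are log-normal
(`meanlog = log(0.05)`, `sdlog = 0.5`, floored at `1e-4`), a mid-range
choice for bulk RNA-seq of sorted tissue; the floor keeps the NB
parameterization valid while allowing a near-Poisson limit for testing.
Per-sample library sizes are uniform on 1–2 million counts over 2000
genes, so a typical gene sits at a few hundred counts — deep enough that
fold-change recovery is limited by biology, not shot noise.

Each sample's expected expression is built in three steps:

1. **Mixing.** Eight epithelial cell types (Stem, TA, late enterocyte
   progenitor, enterocyte, enteroendocrine, goblet, Paneth, tuft) each
   carry a planted profile: a shared per-gene baseline (log2 mean 5, sd 2)
   plus, for each type, a disjoint block of 30 high-expression marker
   genes (baseline uniform on log2 6–9) boosted by 3–5 log2 units in the
   owning type only. A sample's composition is drawn from a
   sample-type-specific Dirichlet; the defaults place stem and TA cells
   high in organoids and differentiated types high in crypts, the
   signature compositional change of ENR-medium culture. The expected
   expression is the composition-weighted mixture of profiles.
2. **Planted effects.** Each factor affects a random gene subset
   (defaults: 30% of genes for sample type, 15% compartment, 10% gender,
   8% age) with random-sign log2 fold changes. Effects act multiplicatively
   on the post-mixture expectation, so expression changes and composition
   changes are separately recoverable. Two-level factors contribute
   `lfc × {0, 1}`; the three compartments contribute a linear gradient
   `lfc × {0, 0.5, 1}` so that the aboral-vs-oral contrast equals the
   planted value exactly.
3. **Scaling.** The expectation is rescaled to the sample's library size
   and read out as NB counts.

When `variance_targets` is set (default: 60/20/12/8% for sample
type/compartment/gender/age), each factor's planted log2FCs are rescaled
analytically so the factors contribute those shares of the total planted
signal variance across the balanced design (per-gene contribution
`lfc² × v`, `v = 1/4` for indicators, `1/6` for the gradient); the total
planted variance is preserved. This is what makes "PC1 should recover the
planted sample-type share" a well-posed check.

In-vitro sharing: for the biology factors, `share_in_vitro ∈ [0, 1]` keeps
that fraction of the affected genes' effects identical in organoids and
re-plants the remainder on fresh genes with fresh magnitudes. The default
is 1 (fully shared); retention analyses lower it to create known partial
retention. An optional `aging_by_gender` interaction adds an extra aging
log2FC in old male crypts only, creating an in-vivo-only aging modifier.

Single-cell data reuse the same profiles and dispersions: 60 cells per
type, library sizes 8–15k, labels returned for scoring.

### What the generator does not emulate

Gene length and GC biases, UMI/droplet artifacts (doublets, ambient RNA),
batch effects beyond the declared factors, mean–variance trends beyond the
log-normal dispersion draw, and any correlation structure between genes
other than that induced by composition and planted effects. Tests passing
on this generator therefore demonstrate that the estimators recover what
was planted under a clean NB world, not that they are robust to every
artifact of real data.

### Determinism

All randomness flows from one root seed through named substreams (design,
profiles, effects, bulk, sc, mixtures, permutations, clustering), so any
stage can be re-run in isolation with identical draws and a full run
reproduces identical stage hashes.

## Normalization and differential expression

Size factors are classic median-of-ratios: per sample, the median over
genes of the count divided by the gene's geometric mean, genes with any
zero excluded. A `use_pseudo_reference` flag computes geometric means over
positive counts only, for matrices where every gene has a zero.

The DE engine is deliberately a *simplified* per-gene NB Wald test, not a
re-implementation of a full GLM framework: downstream analyses consume
only (log2FC, p, adjusted p), and the effect-size models are insensitive
to engine details. Per gene:

- group means of normalized counts estimate the NB means;
- dispersion is method-of-moments on normalized counts
  (`alpha = (s² − mu·mean(1/sf))/mu²`, floored at `1e-8`), then shrunk 50%
  toward a fitted `a0 + a1/mu` mean–dispersion trend — a lightweight
  version of the empirical-Bayes shrinkage used by standard tools;
- the Wald statistic is the log ratio of group means over its delta-method
  standard error (`Var(q̂)/q̂² = Σ(1/s_j)/(n²q̂) + alpha/n` per group),
  two-sided normal p, BH-adjusted within the contrast.

Degenerate inputs: all-zero genes are flagged `tested = FALSE` with NA
statistics rather than dropped; when one group mean is zero, a symmetric
half-count pseudo-mean (`0.5/n` per group) keeps the log ratio finite, and
because it is applied only in that case, a gene constant across all
samples has log2FC exactly 0 and p exactly 1. Swapping the contrast levels
negates every log2FC and leaves p unchanged, exactly.

Stratified contrasts (e.g. old vs young within male/oral/crypt) are
separate single-factor fits on the stratum's samples, with size factors
recomputed within the stratum — there is no interaction model, matching
the pairwise-comparison structure of the analyses these tables feed.

## Variance decomposition

The PCA input keeps genes with IQR of `log2(normalized + 1)` above 1.5 and
mean normalized count above 10 in strictly more than 3 of the 24 condition
groups. Two readings were open here: the IQR scale (raw counts would make
the filter mean-dominated, so the log scale with pseudocount 1 is used)
and the boundary (read strictly: a gene expressed in exactly 3 conditions
fails; both thresholds are arguments).

PCA itself is `prcomp` on samples × genes with genes centered and
unit-scaled; whether to log-transform first is exposed
(`log2_transform`, default TRUE — unscaled normalized counts make the
leading component a depth/magnitude axis). Variance fractions are
`λ_i/Σλ`; per-gene contributions are `100·loading²/Σloading²`, so they sum
to 100 per component. Two numerical conventions make results comparable
across runs: genes are processed in sorted-ID order (so the SVD sees a
canonical matrix regardless of input order), and each component's sign is
fixed by making its largest-magnitude loading positive. Components beyond
the data rank have near-zero eigenvalues and arbitrary directions; only
the well-defined components are comparable.

Highly contributing genes are those with `log2(contribution %) ≥ −3.32`
(≈ 0.1% of a component's squared loadings), sorted descending. An
alternative "density" mode places the cutoff at the knee of the sorted
log2-contribution curve (maximum distance below its chord); the fixed
cutoff is the default because it is reproducible and matches the
contribution-in-percent reading under which uniform loadings over ~500
genes pass and over ~2000 genes fail.

Component–factor association uses Welch's two-tailed t-test for two-level
factors and one-way ANOVA for three or more; levels with fewer than 2
samples are an error, and two groups with identical constant scores return
p = 1 by convention.

## Single-cell reference

Cells are normalized to the median per-cell total after removing
non-expressed genes (zero-total cells are dropped with a warning), then
log10(x + 1) transformed; the linear scale is kept alongside because
signatures and deconvolution mix linearly. k-means (nstart 10, best
inertia) runs on the top 20 PCs of the log matrix — the clustering input
space was unspecified in the source workflow, and PCs both denoise and
decorrelate; `k = n` cells short-circuits to singleton clusters. Targeted
re-clustering of one cluster with k = 2 is supported via the `cells`
argument (the workflow this mirrors separated tuft from enteroendocrine
cells that way).

Clusters are typed by the marker set with the highest mean z-scored
expression; ties within 1e-9 are flagged ambiguous and clusters expressing
no marker at all are flagged unassigned rather than silently broken.
Markers per cluster are genes with log2 fold change ≥ 2 (pseudocount 1 on
linear means) *and* BH-adjusted Welch p < 0.05 on log values against all
other cells — the thresholds are the specification here; the test behind
them is a documented choice (the original "sseq" ranking is not described
in enough detail to clone, and no equivalence is claimed). The signature
matrix holds mean linear-normalized expression of the marker union per
type, columns in declared type order.

## Deconvolution

Bulk samples are size-factor normalized, restricted to signature genes
(an error if more than half are missing), and solved by non-negative least
squares, then renormalized to the simplex; the pre-normalization residual
norm is reported. NNLS was chosen over the support-vector regression of
the popular web tool because the latter is proprietary and not
reproducible from its description; NNLS solves the identical generative
model (`signature · p ≈ bulk, p ≥ 0`) deterministically, and a
grid-search-over-the-simplex oracle bounds its error in the tests.
Estimates are exactly scale invariant and equivariant to column
permutation.

Mixture validation draws Dirichlet compositions (concentration 1),
perturbs the noiseless mixtures with multiplicative log-normal noise of a
given CV (mean 1, a declared noise model — none was specified by the
source), deconvolves, and reports the squared Pearson correlation pooled
over all (mixture, type) pairs, with per-type R² alongside; pooling is the
default because the per-type alternative is also reported. Composition
comparisons are Welch t (crypt vs organoid) and one-way ANOVA (across
compartments within sample type), BH-adjusted across cell types.

Caveat documented by the tests: on bulk samples whose marker genes also
carry planted expression fold changes, deconvolution against an
effect-free signature is biased in the affected condition — the usual
reference-mismatch problem. The simulated-mixture validation, where the
generative model matches the signature, is the clean accuracy statement.

## Enrichment

The running-sum score increments by `|r|^p / Σ_hits |r|^p` on hits and
decrements by `1/(N − |S|)` on misses; the ES is the deviation of largest
magnitude, signed. `p = 1` is the default weighting; `p = 0` with a
tie-free list reduces exactly to the two-sample Kolmogorov–Smirnov
statistic, which is the oracle used in tests. The implementation evaluates
only the running sum's extrema candidates (immediately after each hit,
immediately before each hit — the curve is linear in between), which an
all-prefix brute force verifies exactly. When the maximum and minimum
deviations tie in magnitude, the positive one is reported.

Ranking is by Wald statistic, descending, ties broken lexicographically by
gene ID — the source analysis does not state its ranking metric, so the
default is declared and any finite statistic column can be substituted.
The permutation null redraws `|S|` gene labels (the preranked-tool
convention; phenotype permutation would require re-running DE inside the
loop), `p = (1 + #{|ES_null| ≥ |ES_obs|})/(n + 1)` so p is never zero, BH
across sets. The leading edge collects set members at or before the
maximum (after the minimum, for negative scores).

Directional Z-scores: genes are centered/scaled across samples, multiplied
by ±1 per the set's direction annotation, averaged over the set per
sample, and summarized per group; zero-variance genes are excluded with a
warning. Flipping all directions negates every group mean exactly.

## Effect sizes

DEG matrices hold log2FC where the gene passes the significance rule for
that contrast and exactly 0 otherwise. Two rules are first-class:
adjusted p < 0.05 (feature retention) and raw p < 0.05 (per-stratum aging
matrices, whose n = 8 contrasts would otherwise be nearly empty); the rule
used is recorded as an attribute. Genes significant nowhere are dropped
before model fitting — all-zero rows carry no information and only deflate
R² — with `keep_all = TRUE` to retain them.

Retention of a feature is the adjusted R² of OLS predicting the in vivo
log2FC vector from the in vitro vector (simple) or all three in vitro
vectors (combined), over the zero-filled outer join of both gene sets.
Raw log2FCs enter the regression unscaled: adjusted R² is scale-invariant
for a single predictor, and weighting schemes were left out as
unspecifiable. Collinear predictors and constant outcomes are rejected by
name rather than silently dropped.

The aging-modifier analysis stacks the per-stratum young-vs-old log2FC
columns into long form (one row per gene × stratum) and regresses the
value on the stratum's compartment indicators, gender indicator, or both,
separately in vivo and in vitro. Gene-to-gene variation stays in the
residual by construction, so these adjusted R² are small — they measure
only how much the aging response *differs between strata*, which is the
quantity of interest. A planted in-vivo-only aging-by-gender interaction
raises the in vivo gender modifier above the in vitro one; the magnitude
of that gap scales with the interaction strength and stays modest even
for strong interactions, because the stratum indicators can only explain
the between-stratum mean shift.

## Pipeline and problem sizes

`run_study()` chains all stages (19 DE contrasts: the culture contrast,
per-sample-type compartment/gender/aging, and 12 per-stratum aging fits),
records a manifest of stage hashes, and optionally writes every artifact
with MD5 checksums. The test suite and the acceptance script run the full
default study — 2000 genes × 96 samples, 480 cells — which completes in a
few seconds on one core; calibration checks use 2000 null genes, the
enrichment calibration 200 random sets × 500 permutations, and the
retention grid five studies. These sizes were chosen so every property is
estimated with comfortable precision while a complete suite run stays
interactive.

## Known limitations

- The DE engine's normal-approximation Wald test is calibrated at the
  sample sizes used here (≥ 4 per group, verified at 48 per group) but has
  no exact small-sample guarantee.
- Deconvolution assumes the signature matches the bulk generative process;
  condition-specific expression shifts on marker genes bias the affected
  condition (see above).
- The enrichment module reports raw ES, not set-size-normalized NES, so
  scores are comparable across sets only at equal size.
- The aging-modifier effect sizes are bounded by the stacked-indicator
  design; they are not comparable to the per-gene retention R².
- Real-data artifacts outside the generator's scope (batch, droplet
  artifacts, length/GC bias) are untested by construction.
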