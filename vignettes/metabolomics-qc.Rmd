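---
title: "Pre-analysis quality screening of metabolomics data with metabscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-analysis quality screening of metabolomics data with metabscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Curated metabolomics datasets (NMR or LC-MS panels quantified per sample)
arrive with technical blemishes that should be characterized and, where
appropriate, removed before any statistical analysis: samples that were
mishandled or under-loaded, features measured too sparsely to be useful,
batch-to-batch level shifts, and isolated aberrant values. metabscreen is a
standardized, fully logged pre-analysis workflow for a samples × features
abundance matrix: it computes quality statistics, excludes samples and
features by an ordered, user-parameterized procedure, quantifies how much
technical batch variables explain of the key quality metrics, and writes a
self-contained HTML report so the processing can be disclosed alongside
results.

```{r, eval = FALSE}
library(metabscreen)
demo <- system.file("extdata", "demo", package = "metabscreen")
res <- run_pipeline(matrix = file.path(demo, "abundance.tsv"),
                    meta = file.path(demo, "sample_metadata.tsv"),
                    annotation = file.path(demo, "feature_annotation.tsv"),
                    config = read_config(file.path(demo, "params.txt")),
                    outdir = "demo_out")
res$exclusion_log
```

## The statistics, and why

**Missingness.** Per sample and per feature, the fraction of absent
entries. Sample missingness is reported both over all features and after
excluding *xenobiotics* (exogenous compounds whose absence usually means
true non-exposure rather than technical failure) and, optionally,
*derived measures* (ratios or sums of other features, whose missingness is
inherited from their parents). Xenobiotics are for the same reason exempt
from the missingness-based feature filters at any missingness level.

**Total sum abundance (TSA).** Each retained feature is z-transformed over
its observed values; the standardized matrix is shifted upward by the
absolute value of its global minimum so every entry is non-negative, and
TSA is the per-sample row sum — a proxy for total measured metabolite
content. Two variants are computed: over all features (necessarily
correlated with missingness, since absent entries contribute nothing) and
over complete features only; only the latter is used for exclusion. The
recentring constant is global rather than per-feature: a single shift adds
the same amount to every complete-feature TSA and therefore cannot distort
between-sample comparisons, whereas per-feature shifts would reweight
features by their minima.

**Outlying values.** A cell is flagged when it lies more than
`outlier_iqr_multiplier` (default 5) interquartile ranges from its
feature's median; quantiles use linear interpolation between order
statistics (R's type 7), so for the values 1..9, 100 the IQR is 4.5 and
100 is flagged at the default multiplier. Features with zero IQR flag
nothing. Flag counts are reported per sample and per feature; the values
themselves are never altered in exported data.

**Distribution shape.** Per feature: mean, SD (n−1 denominator), the
adjusted Fisher–Pearson skewness, the coefficient of variation, and
Shapiro–Wilk W on the raw and the log10 scale. Non-positive values are
treated as missing for the log10 variant rather than offset — any
pseudo-count would be arbitrary and changes W materially for
near-zero-inflated features. Above 5000 observations W is computed on a
seeded subsample of 5000 (the estimator's usual range), keeping results
reproducible from the configuration seed.

## Feature reduction and PC outliers

Metabolomics panels contain blocks of highly correlated features (lipid
series, pathway neighbours), which would otherwise dominate a PCA of the
samples. Features that are variable, have ≤ 20% missingness and are not
xenobiotics (nor, optionally, derived) are clustered on the distance
1 − |Spearman's rho| (pairwise-complete observations; pairs sharing fewer
than 3 observations get distance 1) with complete linkage, and the tree is
cut at `tree_cut_height` (default 0.5, i.e. |rho| = 0.5). The number of
clusters is the *effective number of features*, useful for
multiple-testing correction; the least-missing member of each cluster
(ties broken by column order, for reproducibility) becomes its
*representative*, marked `independent_features_binary` in the feature
summary table.

PCs of the samples are computed on the representatives after median
imputation and z-standardization — a deliberately simple imputation, used
only inside this step, that avoids a probabilistic PCA at the cost of some
shrinkage for the more missing features. Component signs are fixed so each
component's largest-magnitude loading is positive, making outputs
byte-reproducible. Two scree-based retention estimates are reported: the
acceleration factor (position of the maximum second difference of the
eigenvalue sequence, minus one, floored at 2; earliest position on ties)
and parallel analysis (count of eigenvalues exceeding the seeded 95th
percentile of 100 standardized Gaussian null matrices of the same shape).
A sample is a PC outlier when, on **any** of the top n components (n from
the acceleration factor), it lies more than `pc_sd_threshold` SD from the
component mean — the "any" reading is the conservative one for quality
control. If isolated extreme values are suspected of driving a sample out,
`pca_outlier_mode` can convert flagged values to missing (then imputed) or
winsorize them to the most extreme unflagged value on the same side —
again only within the PCA working copy.

## The filter pipeline

Steps run in a fixed order, each appended to the exclusion log with its
threshold, counts and removed identifiers: (1) samples with ≥ 80%
missingness; (2) features with ≥ 80% missingness (xenobiotics exempt);
(3) samples at or above `sample_missingness_max` after recomputation;
(4) features at or above `feature_missingness_max` (xenobiotics exempt);
(5) samples more than `tsa_sd_threshold` SD from the mean TSA over
complete features; (6) PC outliers as above, recomputed on the survivors.
Missingness comparisons use ≥, the SD-based comparisons strict >.
Setting a missingness threshold to 0 disables its step (a 0 cut would
otherwise remove everything); the log records "disabled". The exported
filtered matrix keeps original values — imputation and winsorization are
never persisted. Because steps 5–6 recompute means and SDs, strict
idempotence is not guaranteed for borderline data, but re-running the
pipeline on its own output removes nothing on our fixtures.

Derived measures, when excluded, are excluded from the *calculations*
(sample missingness, TSA, PCA eligibility) but retained in the exported
matrix — the user can drop them downstream; their inclusion in the export
preserves the full dataset contract.

## Batch effects, normalization and power

When `batch_normalization_column` names a sample-metadata variable, each
feature × batch cell is scaled by (overall feature median)/(batch median)
*before* any summary or filter, so all within-batch medians agree with
the feature's overall median; multiplicative scaling to the overall median
(rather than to 1) preserves the abundance scale that TSA depends on.
Zero or undefined medians leave the pair unscaled with a warning.

Batch influence on sample missingness and TSA is quantified by
eta-squared (SS_between/SS_total) from one-way ANOVA per variable, and by
type-II sums of squares from an additive model with all batch variables
entered together — "multi-term" is our reading of the multivariate
analysis here, since outcomes are analyzed one at a time; fully aliased
terms are flagged inestimable, and continuous batch descriptors are
rejected rather than silently binned. Power for planned downstream tests
uses the noncentral-t (two-sample, unequal n allowed) and noncentral-F
(general linear model) closed forms, evaluated over fixed effect-size
grids (d = 0.1–1.0; f² ∈ {0.005, 0.01, 0.02, 0.05, 0.1, 0.2}) at
effective sample sizes n(1 − q) for q over the observed feature
missingness quantiles — showing what missing data costs in power.

## The synthetic study data

`generate_fixture()` produces the seeded datasets used throughout the
tests: 200 samples × 60 features by default, with 3 blocks of features
sharing a latent factor (correlation 0.95), log-normal marginals with
log-scale SDs of 0.15–0.4 (typical metabolomics CVs of roughly 15–40%),
2 batches with per-feature multiplicative shifts up to 1.25×, ~5% missing
core cells, 5 presence/absence xenobiotics (~85% missing), 5 derived
ratio features that inherit parent missingness, 10 planted outlier cells
(8 IQR), 2 samples at 85% missingness, 1 sample with a global ×10 shift
(a handling-error signature caught by the TSA filter) and 1 sample
perturbed on two representative features in opposite directions — large
on the leading PCs but TSA-neutral, so it is caught at the PC step and
nowhere earlier. Missingness is planted on alternating features within
each block so that each block keeps complete members, and the
high-missingness samples' missing sets avoid the representative-to-be of
each block, which makes the planted design exactly recoverable.

What the generator does **not** emulate: missingness that depends on
abundance (left-censoring at the detection limit), within-batch drift,
heteroscedastic technical noise, and correlated missingness across
samples. Passing the planted-recovery tests therefore demonstrates the
machinery is correct, not that real data will separate as cleanly;
threshold choices on real data should follow an inspection of the report.

## Numerical choices and problem sizes

Quantiles are type 7 everywhere; SDs use the n−1 denominator; Spearman
correlations use pairwise-complete observations; undefined correlations
map to maximal distance; zero-variance features are dropped from TSA and
PCA with warnings rather than errors. All randomness (parallel-analysis
nulls, Shapiro subsampling, the cosmetic k-means in the report) flows
from `rng_seed`, and floating-point output uses 12 significant digits, so
identical inputs give byte-identical outputs (the per-feature PDF has its
embedded timestamps overwritten with a fixed placeholder for the same
reason). Test and demonstration datasets are kept at 25–400 samples and
10–60 features — ample for the planted designs while keeping the full
suite fast; the same code paths run unchanged on cohort-scale matrices.

## Known limitations

The pipeline does not impute, transform or batch-correct the data it
exports — it only characterizes, filters and reports, and the parameter
file's key names are this package's own convention. SD-from-mean
exclusion rules (TSA, PCs) assume an approximately unimodal, homogeneous
sample; for case–control extremes, mixed tissues or strongly structured
populations the report's distributions should be inspected and the
thresholds relaxed or disabled rather than applied blindly.
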