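---
title: "Transcriptomic distance ratios: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic distance ratios: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the quantity

A metastatic tumor grows in an organ that is not the one it came from. This
package quantifies, for bulk or single-cell expression cohorts, whether a
tumor sample's transcriptome sits closer to its normal **origin tissue**
(OT) or to its normal metastatic **target tissue** (TT).

The primitive is the transcriptomic distance (TD). For a sample vector $x$
and a tissue reference profile $y$ over the same genes,

$$\mathrm{TD}(x, y) = \lVert z(\log_2(x + 1)) - z(\log_2(y + 1)) \rVert_2,$$

where $z(\cdot)$ is the z-score with the $n-1$ standard deviation. The
pseudocount of 1 is skipped for data already in log space. Standardizing
the log vectors makes the distance invariant to per-sample multiplicative
rescaling (library size, unit changes), and links the Euclidean measure to
the Pearson correlation $r$ of the log vectors through the exact identity

$$\mathrm{TD}^2 = 2(n-1)(1 - r),$$

which the test suite uses as an independent oracle. Two further measures,
$1 - \rho_{\text{Spearman}}$ on the log values and $1 - \cos$ on the
standardized vectors, are provided for robustness checks; both are
conventions of this package, chosen so that all three measures vanish when
the sample equals the reference.

The **TD ratio** of a tumor sample is
$\mathrm{TD}(x, \mathrm{OT}) / \mathrm{TD}(x, \mathrm{TT})$: above 1 means
closer to the target tissue, below 1 closer to the origin. Reference
profiles are per-gene medians over a tissue's normal samples (means for
single-cell data, where sparsity makes medians collapse toward zero).

Degenerate denominators are never exceptions: a sample coinciding with the
TT reference yields a flagged `Inf` sentinel (ratio 1 if it coincides with
both), and cohort-level aggregation drops flagged samples. This keeps
batch computation total while making degeneracy visible.

## Specificity, PMT scores, and purity

**Specificity.** To ask whether metastases shift toward their *true*
target rather than any foreign tissue, the sample-dependent numerator is
replaced by the constant reference-to-reference distance:
$\mathrm{TD}(\mathrm{OT}, \mathrm{TT}) / \mathrm{TD}(x, \mathrm{TT})$.
This normalized ratio is comparable across candidate target tissues whose
baseline similarity to the origin differs. For each candidate, a one-sided
Wilcoxon signed-rank test (paired across the same samples) asks whether
the true target's ratios are higher; the specificity score counts
candidates beaten at BH FDR < 0.1. A candidate identical to the true
target produces all-zero paired differences, which we score as p = 1 so
ties contribute nothing.

**PMT score.** For paired cohorts,
$\mathrm{ED}(\text{met}, \text{primary}) / \mathrm{ED}(\text{met}, \mathrm{TT})$
asks whether a metastasis has moved closer to its target tissue than to
its own primary. It uses the Euclidean measure by definition.

**Purity.** Bulk tumor samples are a mixture of malignant and normal
cells, and the normal fraction pulls the transcriptome toward the origin
tissue, confounding TD ratios. Purity enters as an input column. The
decision rule: Spearman's correlation between ratio and purity is tested
separately within the primary and the metastatic class; if either is
significant at p < 0.05, the dataset's ratios are replaced by the
residuals of the pooled OLS fit `ratio ~ purity`. Pooling the classes for
the fit (while testing per class) was a genuinely open choice; we pool
because the adjustment is a dataset-level replacement and a pooled fit
keeps primary and metastatic residuals on one scale. Residuals have mean
zero and no linear purity component, and residualizing twice is a no-op.

## Pathway-level analysis

Restricting all vectors to a pathway's genes (re-standardizing within the
subset) gives pathway-specific TD ratios and PMT scores. A pathway is
analyzed only if at least 90% of its genes are present in the harmonized
data (70% for sparse single-cell data), with an inclusive boundary.
Groups are (cancer type, primary/metastatic class, target tissue) cells
with at least three samples.

The **delta** value divides the group's median pathway-specific value by
the same group's all-genes median, isolating pathway-level shifts from
whole-transcriptome drift: delta > 1 means the pathway sits closer to the
target tissue than the transcriptome as a whole does.

Significance comes from an empirical null: for each pathway, `n_iter`
random gene sets of the same size are drawn from the harmonized gene
universe and their deltas computed in the same group. With $r$ null deltas
at least as large as the observed one,

$$P = \frac{r + 1}{n + 1},$$

folded two-sided as $\min(P, 1 - P)$ — a pathway can be significantly
shifted toward either tissue — and BH-adjusted across all rows of one
invocation (the FDR family is the invocation; this is recorded in the
output). The default is `n_iter = 10000` with seed 1206; the bundled
analyses use 1000–2000 iterations, which resolves p-values to 5e-4 — ample
for an FDR threshold of 0.1. Pathways of equal size within a group share
one null set of draws: the null distribution depends only on (group,
size), so this is exact re-use, not an approximation.

## Enrichment between primary and metastatic samples

Per-gene scores are $\log_2$ fold changes of geometric means (metastatic
over primary), computed as differences of mean log2 values with the
pseudocount added before the mean so zero counts are defined.

Pre-ranked enrichment uses the classic weighted Kolmogorov–Smirnov running
sum (hit increments proportional to |score|, uniform miss decrements; the
ES is the extremum, positive winning ties). The null permutes genes:
random same-size sets, matching the random-gene-set philosophy of the
pathway analysis; NES is ES divided by the mean |null ES| of the same
sign, and p-values are $(r+1)/(n+1)$ within the same-sign null. This is a
plain permutation scheme, not an adaptive multilevel estimator; no
equivalence to such estimators is claimed, and the permutation count
bounds the smallest reportable p at $1/(n_{\text{perm}}+1)$. A control
routine scores many random sets and reports the significant fraction and
direction split, which on null data should sit near the nominal level and
50/50.

Single-sample activity uses a rank-ECDF score in the ssGSEA family:
genes are ranked within each sample, and the score is the normalized area
between the rank-weighted in-set ECDF (weights $\mathrm{rank}^{\tau}$,
$\tau = 0.25$) and the uniform out-set ECDF. We deliberately do **not**
re-implement kernel-density activity scoring: downstream use is purely
between-group Wilcoxon rank-sum comparison, which is invariant to the
choice of monotone score, so a transparent rank-based score is preferable
to a reimplementation of a more elaborate one. The score itself is
invariant to any strictly monotone transform of a sample's values, which
the tests assert.

## Statistical machinery

Paired comparisons use one-sided Wilcoxon signed-rank tests; unpaired
ones, one-sided rank-sum tests. Zero differences are dropped (logged).
Tie-free samples below 50 use the exact distributions; ties fall back to
midranks with a continuity-corrected normal approximation — the
convention of the standard R implementation, which the package wraps. The
test suite verifies exactness against brute-force enumeration of all
$2^n$ sign vectors and all $\binom{m+n}{m}$ group assignments. Multiple
testing uses Benjamini–Hochberg throughout, with 0.1 as the default FDR
threshold.

## What the synthetic generator emulates

The generator provides ground truth for every stage. Each tissue has a
per-gene log2 mean: a shared baseline $\mathcal{N}(5, 2^2)$ plus
`separation` (default 1) times a tissue-specific standard normal
displacement, with 10% of genes silenced per tissue. Tumor samples mix
the origin and target log-means with weight $\alpha$ —
$(1-\alpha)\,\mu_{\mathrm{OT}} + \alpha\,\mu_{\mathrm{TT}}$ — plus a
cohort-level tumor-specific offset (scale 0.5) and per-sample
$\mathcal{N}(0, 0.5^2)$ log noise. Defaults: 2000 genes, 20 normals per
tissue, 20 patients per cohort, $\alpha = 0.15$ for primaries and 0.45
for metastases, so primaries stay near their origin while metastases
shift without crossing it — the qualitative structure the analysis is
designed to detect. These values were chosen once as a realistic regime
for z-scored log-expression distances and are not tuned per analysis;
$\alpha_{\text{met}} > \alpha_{\text{primary}}$ is a default, not a
constraint, so no-shift null cohorts are generable.

Purity confounding mixes each observed sample with the clean OT profile
on the linear scale, `observed = purity * tumor + (1 - purity) * OT`,
with purity drawn from Beta(6, 2) (mean 0.75). This induces a positive
ratio–purity slope for the residualization stage to find and remove.
Pathway shifts are planted by re-drawing only a gene set's rows at a
higher mixture weight $\alpha_p$ (default 0.9 in the bundled analyses),
re-applying the sample's purity mixing.

What the generator does **not** emulate: single-cell dropout, batch
effects, count overdispersion structure, correlated gene modules, or
inter-patient heterogeneity in $\alpha$. Passing tests therefore
demonstrate that the estimators recover the planted structure under the
stated noise model — not that real cohorts satisfy that model.

## Numerical choices and problem sizes

* 75th percentiles use the type-7 (linear interpolation) quantile; the
  convention is stated because upper-quartile normalization divides by it.
* TMM-CPM normalization delegates to edgeR's `calcNormFactors`; the test
  oracle is an independent direct implementation of the published trimmed
  mean of M-values procedure (30%/5% trims, precision weights, reference
  sample by upper quartile closest to the mean, factors rescaled to
  geometric mean 1).
* Duplicate gene rows collapse by mean with a warning; duplicate sample
  ids are errors. Variable-gene selection uses variance of pooled
  log2(x+1) values with lexicographic tie-breaks. Pseudo-sample ids are
  `original::TT`, reversible by splitting on `::`.
* Calibration and recovery checks run at reduced but statistically
  adequate sizes chosen for the package's test suite: null calibration
  uses two cancer types x two classes x 200 pathways at 2000 iterations
  (800 p-values, where the expected Kolmogorov–Smirnov distance under
  perfect calibration is about 0.03); planted-pathway recovery runs the
  default generator with 1000 iterations; the mixture-weight monotonicity
  check uses 20 seeds over the grid {0, 0.25, 0.5, 0.75, 1}.

## Limitations

The pipeline compares samples to tissue-level central profiles; it does
not model per-gene differential expression, cell-type composition beyond
the scalar purity term, or pathway topology. Spearman- and cosine-based
distances are supported for whole-transcriptome ratios but PMT scores are
Euclidean by definition. The empirical null conditions on the observed
group structure, so its guarantees are per-invocation, not across
re-analyses with different group definitions.
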