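# tdratio

Quantifying whether primary and metastatic tumors are transcriptionally
closer to their normal tissue of origin (OT) or to their metastatic
target tissue (TT), at whole-transcriptome and pathway resolution.

Metastases must survive in an organ that is not the one they came from.
For a tumor expression vector $x$ and a tissue reference profile $y$
(per-gene median over that tissue's normal samples), the transcriptomic
distance is the Euclidean distance between z-scored log2 vectors,
$\mathrm{TD}(x,y) = \lVert z(\log_2 x) - z(\log_2 y)\rVert_2$, and the
**TD ratio**

$$\frac{\mathrm{TD}(x, \mathrm{OT})}{\mathrm{TD}(x, \mathrm{TT})}$$

is below 1 when the sample still resembles its origin and above 1 when it
has shifted toward its target. Around this primitive the package builds:

- per-sample TD ratios (Euclidean, Spearman- and cosine-based measures)
  with paired/unpaired one-sided Wilcoxon group comparisons and BH FDR;
- **organotropism specificity**: normalized TD ratios
  $\mathrm{TD}(\mathrm{OT},\mathrm{TT}) / \mathrm{TD}(x,\mathrm{TT})$
  across candidate target tissues, scored by how many candidates the true
  target beats at FDR < 0.1;
- **tumor purity control**: Spearman screening of ratio~purity per class
  and OLS residualization when confounded (p < 0.05);
- **pathway-level Δ ratios and Δ PMT scores**: a pathway's group median
  divided by the all-genes median, with empirical p-values
  $P = (r+1)/(n+1)$ from random same-size gene sets, folded two-sided as
  $\min(P, 1-P)$, BH-corrected;
- **enrichment**: geometric-mean log2 fold changes, pre-ranked
  running-sum enrichment with a random-gene-set null (NES, FDR,
  direction), a rank-ECDF single-sample activity score, and a random-set
  direction-bias control;
- a **synthetic cohort generator** (lognormal tissue model, tunable
  OT→TT mixture weight α, planted pathway shifts, purity confounding)
  that provides ground truth for every stage.

See `vignettes/methods.Rmd` for the model, estimator conventions, and
design decisions.

## Worked example

The numbered drivers under `analysis/` run the full study on a synthetic
colon→liver cohort (20 patients, paired; primaries mixed 15% toward the
liver, metastases 45%; three planted pathway shifts at α = 0.9):

```sh
Rscript analysis/01_simulate.R          # fixture bundle -> scratch/fixture/
Rscript analysis/02_td_ratios.R         # whole-transcriptome TD ratios
Rscript analysis/03_specificity_purity.R
Rscript analysis/04_pathway_scores.R
Rscript analysis/05_enrichment.R
```

Output of `02_td_ratios.R`:

```
median TD ratio: primary 0.509, metastatic 1.002
paired one-sided signed-rank (met > pri): p = 9.54e-07 (metastatic_greater, 20 pairs)
raw distance to target (met < pri): p = 9.54e-07
```

Both classes sit at or below the equipoise value of 1 — tumors keep
resembling their origin — but the metastases have moved significantly
closer to the liver than their paired primaries, which is the structure
the generator plants. `03_specificity_purity.R` shows the shift is
specific to the true target tissue and that purity confounding is
detected and removed:

```
specificity: true TT 'liver' beats 5 of 5 candidates (score = 5)
ratio~purity Spearman rho = 0.602 (p = 5.94e-06) -> residualizing
after residualization: |rho| = 0.002
```

and `04_pathway_scores.R` recovers exactly the planted pathway shifts:

```
delta TD ratios: planted recovered 6/6 rows at FDR < 0.1; 0/34 unplanted flagged
delta PMT scores: planted recovered 3/3 rows at FDR < 0.1; 0/17 unplanted flagged
```

Result tables are written under `results/`.

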