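#!/usr/bin/env Rscript
# Hallmark-style activity comparison between primary and metastatic
# samples: geometric-mean fold changes, pre-ranked enrichment with a
# random-set direction-bias control, and the rank-based single-sample
# activity comparison.

library(tdratio)

tumor <- read_expression_matrix("scratch/fixture/tumor_expression.tsv", "cpm")
ann <- read_sample_annotation("scratch/fixture/sample_annotation.tsv")
sets <- read_gene_sets_gmt("scratch/fixture/gene_sets.gmt")

pri <- ann$sample_id[ann$role == "primary"]
met <- ann$sample_id[ann$role == "metastatic"]
fc <- geometric_log2_fold_change(tumor[, pri], tumor[, met])
gsea <- preranked_gsea(fc, sets, n_perm = 2000, seed = 1206)
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
write.table(gsea, "results/enrichment/gsea.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d/%d sets enriched at FDR < 0.1 (%d metastatic-, %d primary-directed)",
                sum(gsea$fdr < 0.1), nrow(gsea),
                sum(gsea$fdr < 0.1 & gsea$nes > 0),
                sum(gsea$fdr < 0.1 & gsea$nes < 0)))

ctrl <- random_set_enrichment_control(fc, n_sets = 500, sizes = c(25, 50, 100),
                                      n_perm = 500, seed = 1207)
write.table(ctrl$summary, "results/enrichment/random_set_control.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("random-set control: %.1f%% significant, %.1f%% positive direction",
                100 * ctrl$summary$frac_significant,
                100 * ctrl$summary$frac_positive))

act <- single_sample_activity(tumor[, c(pri, met)], sets)
groups <- stats::setNames(ann$role, ann$sample_id)[c(pri, met)]
cmp <- compare_group_activity(act, groups)
write.table(cmp, "results/enrichment/activity_comparison.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("activity comparison: %d/%d sets differ at FDR < 0.1",
                sum(cmp$fdr < 0.1), nrow(cmp)))
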