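#!/usr/bin/env Rscript
# Organotropism specificity: do the metastases shift toward their true
# target tissue specifically, or toward any foreign tissue? Also
# demonstrates the purity confounder rule on a purity-mixed cohort.

library(tdratio)

cfg <- simulation_config(n_genes = 600,
                         tissues = c("colon", "liver", "lung", "brain",
                                     "ovary", "skin", "kidney"),
                         n_normals = 10, n_patients = 20, alpha_met = 0.8,
                         seed = 1206)
ref <- generate_reference_cohort(cfg)
tum <- generate_tumor_cohort(cfg, ref, "colon", "liver")
refs <- lapply(stats::setNames(cfg$tissues, cfg$tissues), function(t) {
  build_reference_profile(
    ref$matrix, ref$annotation$sample_id[ref$annotation$origin_tissue == t],
    tissue = t)
})
mets <- tum$annotation$sample_id[tum$annotation$role == "metastatic"]
spec <- specificity_analysis(tum$matrix, mets, refs$colon,
                             refs[setdiff(names(refs), "colon")], "liver")
print(spec)
dir.create("results/specificity", showWarnings = FALSE, recursive = TRUE)
write.table(spec$table, "results/specificity/specificity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# Purity: regenerate the cohort with purity mixing switched on, show the
# induced ratio~purity association and its removal by residualization.
cfg_p <- simulation_config(n_genes = 600, tissues = c("colon", "liver"),
                           n_normals = 10, n_patients = 25,
                           purity_mixing = TRUE, seed = 1207)
ref_p <- generate_reference_cohort(cfg_p)
tum_p <- generate_tumor_cohort(cfg_p, ref_p, "colon", "liver")
refs_p <- lapply(stats::setNames(cfg_p$tissues, cfg_p$tissues), function(t) {
  build_reference_profile(
    ref_p$matrix, ref_p$annotation$sample_id[ref_p$annotation$origin_tissue == t],
    tissue = t)
})
td <- cohort_td_ratios(tum_p$matrix, tum_p$annotation, refs_p)
pur <- tum_p$annotation$purity[match(td$sample_id, tum_p$annotation$sample_id)]
assoc <- purity_association(td$ratio, pur)
message(sprintf("ratio~purity Spearman rho = %.3f (p = %.3g) -> %s",
                assoc$rho, assoc$p,
                if (assoc$p < 0.05) "residualizing" else "no adjustment"))
if (assoc$p < 0.05) {
  residuals <- purity_residualize(td$ratio, pur)
  message(sprintf("after residualization: |rho| = %.3f",
                  abs(suppressWarnings(cor(residuals, pur, method = "spearman")))))
}
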